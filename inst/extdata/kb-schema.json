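{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "redeye knowledge base",
  "description": "Schema for the YAML knowledge-base files read by redeye::read_kb(). A KB defines the diagnosis ontology, the question bank with per-diagnosis conditional YES probabilities and ordering constraints, management advice rules, and engine settings.",
  "type": "object",
  "required": ["diagnoses", "questions"],
  "properties": {
    "diagnoses": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["id"],
        "properties": {
          "id": {"type": "string", "description": "short stable identifier, unique within the KB"},
          "name": {"type": "string", "description": "display name; defaults to id"},
          "urgent": {"type": "boolean", "description": "requires rapid specialist referral", "default": false},
          "prior": {"type": "number", "minimum": 0, "description": "relative pre-test weight; renormalized to sum to 1 on load", "default": 1}
        }
      }
    },
    "questions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "text", "yes_prob"],
        "properties": {
          "id": {"type": "string"},
          "text": {"type": "string", "pattern": "\\?$"},
          "opening": {"type": "boolean", "description": "member of the fixed opening set asked before dynamic selection", "default": false},
          "yes_prob": {
            "type": "object",
            "description": "map diagnosis id -> P(YES | diagnosis) in [0,1]; the special key 'default' covers unlisted diagnoses; 0 (1) encodes a hard rule-out on YES (NO); every diagnosis must be covered explicitly or by 'default'",
            "additionalProperties": {"type": "number", "minimum": 0, "maximum": 1}
          },
          "prerequisites": {
            "type": "array",
            "description": "all pairs must already be answered as stated before this question becomes eligible",
            "items": {"$ref": "#/$defs/answerPair"}
          },
          "redundancy_triggers": {
            "type": "array",
            "description": "any answered pair permanently eliminates this question from the bank",
            "items": {"$ref": "#/$defs/answerPair"}
          }
        }
      }
    },
    "advice": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "conditions", "message"],
        "properties": {
          "id": {"type": "string"},
          "conditions": {
            "type": "array",
            "description": "conjunction of answered pairs; the rule fires at most once per session, the first time all hold",
            "items": {"$ref": "#/$defs/answerPair"}
          },
          "diagnosis": {"type": "string", "description": "optional: also require a minimum posterior for this diagnosis"},
          "min_posterior": {"type": "number", "minimum": 0, "maximum": 1},
          "message": {"type": "string", "minLength": 1}
        }
      }
    },
    "settings": {
      "type": "object",
      "properties": {
        "theta": {"type": "number", "minimum": 1, "default": 5, "description": "dominance ratio: stop when top posterior >= theta x second posterior"},
        "stop_posterior": {"type": "number", "minimum": 0, "maximum": 1, "default": 0.5, "description": "posterior floor the top diagnosis must also reach for a dominance stop"},
        "voi_mode": {"enum": ["max", "expected"], "default": "max", "description": "aggregate the per-answer total-variation distances by max or by expectation"}
      }
    }
  },
  "$defs": {
    "answerPair": {
      "type": "object",
      "required": ["question", "answer"],
      "properties": {
        "question": {"type": "string", "description": "question id"},
        "answer": {"enum": ["yes", "no"]}
      }
    }
  }
}
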