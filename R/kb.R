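#' Read a diagnostic knowledge base from a YAML file
#'
#' A knowledge base (KB) bundles everything the engine needs: the diagnosis
#' ontology (with urgency flags and prior weights), the question bank (with
#' per-diagnosis conditional YES probabilities, prerequisite and redundancy
#' constraints, and the fixed opening set), management advice rules, and
#' engine settings. The on-disk format is a human-editable YAML document;
#' a machine-readable schema ships in
#' `system.file("extdata", "kb-schema.json", package = "redeye")`.
#'
#' Prior weights are relative pre-test prevalences and are renormalized to
#' sum to 1 on load. A conditional probability of exactly 0 (or 1) encodes a
#' hard rule-out on a YES (or NO) answer.
#'
#' @param path Path to a KB YAML file.
#' @return A validated `redeye_kb` object: a list of tibbles
#'   (`diagnoses`, `questions`, `advice`) plus a `settings` list.
#' @seealso [validate_kb()], [write_kb()], [default_kb()]
#' @examples
#' kb <- default_kb()
#' kb$diagnoses
#' @export
read_kb <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("KB file not found: ", path), class = "redeye_kb_io_error")
  }
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      abort(paste0("KB file does not parse as YAML: ", conditionMessage(e)),
            class = "redeye_kb_parse_error")
    }
  )
  kb <- kb_from_list(raw)
  report <- validate_kb(kb)
  if (nrow(report) > 0) {
    abort(
      paste0(
        "KB failed validation:\n",
        paste0("  - [", report$location, "] ", report$problem, collapse = "\n")
      ),
      class = "redeye_kb_invalid"
    )
  }
  kb$diagnoses$prior <- kb$diagnoses$prior / sum(kb$diagnoses$prior)
  kb
}

# Build a redeye_kb from a plain nested list (parsed YAML). Performs only
# structural coercion; semantic checks live in validate_kb().
kb_from_list <- function(raw) {
  schema_fail <- function(field) {
    abort(paste0("KB schema error: missing or malformed field '", field, "'"),
          class = "redeye_kb_parse_error")
  }
  if (!is.list(raw)) schema_fail("<document root>")
  for (key in c("diagnoses", "questions")) {
    if (is.null(raw[[key]]) || !is.list(raw[[key]])) schema_fail(key)
  }

  dx <- map(raw$diagnoses, function(d) {
    if (is.null(d$id)) schema_fail("diagnoses[].id")
    tibble(
      id     = as.character(d$id),
      name   = as.character(d$name %||% d$id),
      urgent = isTRUE(d$urgent),
      prior  = as.numeric(d$prior %||% 1)
    )
  })
  diagnoses <- list_rbind(dx)

  qs <- map(raw$questions, function(q) {
    if (is.null(q$id)) schema_fail("questions[].id")
    probs <- q$yes_prob %||% list()
    default <- probs[["default"]]
    probs[["default"]] <- NULL
    tibble(
      id          = as.character(q$id),
      text        = as.character(q$text %||% q$id),
      opening     = isTRUE(q$opening),
      yes_prob    = list(unlist(probs) %||% setNames(numeric(0), character(0))),
      yes_default = as.numeric(default %||% NA_real_),
      prerequisites = list(pair_table(q$prerequisites)),
      redundancy    = list(pair_table(q$redundancy_triggers))
    )
  })
  questions <- list_rbind(qs)

  adv <- map(raw$advice %||% list(), function(a) {
    if (is.null(a$id)) schema_fail("advice[].id")
    tibble(
      id            = as.character(a$id),
      message       = as.character(a$message %||% ""),
      conditions    = list(pair_table(a$conditions)),
      diagnosis     = as.character(a$diagnosis %||% NA_character_),
      min_posterior = as.numeric(a$min_posterior %||% NA_real_)
    )
  })
  advice <- if (length(adv)) {
    list_rbind(adv)
  } else {
    tibble(id = character(), message = character(), conditions = list(),
           diagnosis = character(), min_posterior = numeric())
  }

  s <- raw$settings %||% list()
  settings <- list(
    theta          = as.numeric(s$theta %||% 5),
    stop_posterior = as.numeric(s$stop_posterior %||% 0.5),
    voi_mode       = as.character(s$voi_mode %||% "max")
  )

  structure(
    list(diagnoses = diagnoses, questions = questions, advice = advice,
         settings = settings),
    class = "redeye_kb"
  )
}

# (question, answer) pair lists appear in prerequisites, redundancy
# triggers and advice conditions; YAML spells them as {question: q, answer: yes}
pair_table <- function(x) {
  if (is.null(x) || length(x) == 0) {
    return(tibble(question = character(), answer = character()))
  }
  list_rbind(map(x, function(p) {
    a <- p$answer %||% NA
    # YAML reads bare yes/no as logicals
    if (is.logical(a)) a <- if (isTRUE(a)) "yes" else "no"
    tibble(question = as.character(p$question %||% NA_character_),
           answer   = tolower(as.character(a)))
  }))
}

#' Validate a knowledge base
#'
#' Checks every structural invariant the engine relies on: unique ids,
#' resolvable references, probabilities in \[0, 1\], complete answer models
#' (explicit per-diagnosis value or a declared default), acyclic
#' prerequisites, and sane settings. Produces a report rather than failing,
#' so a KB author can fix all problems in one pass.
#'
#' @param kb A `redeye_kb` object (typically from [read_kb()] or built
#'   programmatically).
#' @return A tibble with columns `location` and `problem`; zero rows iff the
#'   KB is valid.
#' @examples
#' validate_kb(default_kb())  # 0 rows
#' @export
validate_kb <- function(kb) {
  stopifnot(inherits(kb, "redeye_kb"))
  probs <- list()
  add <- function(location, problem) {
    probs[[length(probs) + 1]] <<- tibble(location = location, problem = problem)
  }

  dx <- kb$diagnoses
  qs <- kb$questions

  if (nrow(dx) == 0) add("diagnoses", "no diagnoses defined")
  if (anyDuplicated(dx$id)) {
    add("diagnoses", paste0("duplicate diagnosis id(s): ",
                            paste(unique(dx$id[duplicated(dx$id)]), collapse = ", ")))
  }
  if (any(is.na(dx$prior) | dx$prior < 0)) {
    add("diagnoses", "priors must be nonnegative numbers")
  } else if (nrow(dx) > 0 && sum(dx$prior) <= 0) {
    add("diagnoses", "at least one diagnosis must have prior > 0")
  }

  if (anyDuplicated(qs$id)) {
    add("questions", paste0("duplicate question id(s): ",
                            paste(unique(qs$id[duplicated(qs$id)]), collapse = ", ")))
  }

  for (i in seq_len(nrow(qs))) {
    qid <- qs$id[i]
    loc <- paste0("questions/", qid)
    if (!nzchar(qs$text[i]) || !grepl("\\?$", qs$text[i])) {
      add(loc, "question text must be non-empty and end with '?'")
    }
    p <- qs$yes_prob[[i]]
    bad_ref <- setdiff(names(p), dx$id)
    if (length(bad_ref)) {
      add(loc, paste0("answer model references unknown diagnosis id(s): ",
                      paste(bad_ref, collapse = ", ")))
    }
    if (length(p) && any(is.na(p) | p < 0 | p > 1)) {
      add(loc, "answer model probabilities must lie in [0, 1]")
    }
    d <- qs$yes_default[i]
    if (!is.na(d) && (d < 0 || d > 1)) {
      add(loc, "default answer probability must lie in [0, 1]")
    }
    if (is.na(d)) {
      missing <- setdiff(dx$id, names(p))
      if (length(missing)) {
        add(loc, paste0("answer model omits diagnosis id(s) with no default: ",
                        paste(missing, collapse = ", ")))
      }
    }
    for (col in c("prerequisites", "redundancy")) {
      tab <- qs[[col]][[i]]
      bad_q <- setdiff(tab$question, qs$id)
      if (length(bad_q)) {
        add(loc, paste0(col, " reference unknown question id(s): ",
                        paste(bad_q, collapse = ", ")))
      }
      bad_a <- setdiff(tab$answer, c("yes", "no"))
      if (length(bad_a)) {
        add(loc, paste0(col, " answers must be yes/no, got: ",
                        paste(bad_a, collapse = ", ")))
      }
    }
  }

  cyc <- prerequisite_cycle(qs)
  if (!is.null(cyc)) {
    add("questions", paste0("prerequisite cycle: ", paste(cyc, collapse = " -> ")))
  }

  for (i in seq_len(nrow(kb$advice))) {
    a <- kb$advice[i, ]
    loc <- paste0("advice/", a$id)
    if (!nzchar(a$message)) add(loc, "advice message must be non-empty")
    bad_q <- setdiff(a$conditions[[1]]$question, qs$id)
    if (length(bad_q)) {
      add(loc, paste0("condition references unknown question id(s): ",
                      paste(bad_q, collapse = ", ")))
    }
    if (!is.na(a$diagnosis) && !(a$diagnosis %in% dx$id)) {
      add(loc, paste0("unknown diagnosis id: ", a$diagnosis))
    }
    if (!is.na(a$min_posterior) && (a$min_posterior < 0 || a$min_posterior > 1)) {
      add(loc, "min_posterior must lie in [0, 1]")
    }
  }

  s <- kb$settings
  if (!is.numeric(s$theta) || is.na(s$theta) || s$theta < 1) {
    add("settings", "theta (dominance ratio) must be >= 1")
  }
  if (!is.numeric(s$stop_posterior) || is.na(s$stop_posterior) ||
      s$stop_posterior < 0 || s$stop_posterior > 1) {
    add("settings", "stop_posterior must lie in [0, 1]")
  }
  if (!(s$voi_mode %in% c("max", "expected"))) {
    add("settings", "voi_mode must be 'max' or 'expected'")
  }

  if (length(probs)) list_rbind(probs) else {
    tibble(location = character(), problem = character())
  }
}

# Depth-first search over prerequisite edges; returns one cycle (as a path of
# question ids) or NULL.
prerequisite_cycle <- function(qs) {
  edges <- setNames(map(seq_len(nrow(qs)), function(i) {
    intersect(qs$prerequisites[[i]]$question, qs$id)
  }), qs$id)
  state <- setNames(rep(0L, nrow(qs)), qs$id)  # 0 new, 1 in-stack, 2 done
  found <- NULL
  visit <- function(id, path) {
    if (!is.null(found)) return(invisible())
    if (state[[id]] == 1L) {
      found <<- c(path[which(path == id)[1]:length(path)], id)
      return(invisible())
    }
    if (state[[id]] == 2L) return(invisible())
    state[[id]] <<- 1L
    for (dep in edges[[id]]) visit(dep, c(path, id))
    state[[id]] <<- 2L
  }
  for (id in qs$id) visit(id, character(0))
  found
}

#' Write a knowledge base back to YAML
#'
#' Serialization is lossless: `read_kb(write_kb(kb, path))` reproduces the
#' same KB (priors are stored normalized once loaded).
#'
#' @param kb A `redeye_kb` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kb <- function(kb, path) {
  stopifnot(inherits(kb, "redeye_kb"))
  pairs_out <- function(tab) {
    if (nrow(tab) == 0) return(NULL)
    pmap(tab, function(question, answer) list(question = question, answer = answer))
  }
  out <- list(
    diagnoses = pmap(kb$diagnoses, function(id, name, urgent, prior) {
      list(id = id, name = name, urgent = urgent, prior = prior)
    }),
    questions = pmap(kb$questions, function(id, text, opening, yes_prob,
                                            yes_default, prerequisites, redundancy) {
      yp <- as.list(yes_prob)
      if (!is.na(yes_default)) yp$default <- yes_default
      q <- list(id = id, text = text, opening = opening, yes_prob = yp)
      pre <- pairs_out(prerequisites)
      red <- pairs_out(redundancy)
      if (!is.null(pre)) q$prerequisites <- pre
      if (!is.null(red)) q$redundancy_triggers <- red
      q
    }),
    advice = pmap(kb$advice, function(id, message, conditions, diagnosis,
                                      min_posterior) {
      a <- list(id = id, message = message, conditions = pairs_out(conditions))
      if (!is.na(diagnosis)) a$diagnosis <- diagnosis
      if (!is.na(min_posterior)) a$min_posterior <- min_posterior
      a
    }),
    settings = kb$settings
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' The default red-eye knowledge base
#'
#' Loads the KB shipped with the package: 15 ocular diagnoses (4 flagged
#' urgent: corneal ulcer, acute angle-closure glaucoma, iritis, and
#' endophthalmitis/severe inflammation), a 21-question bank built from
#' bedside findings available without a slit lamp exam, and referral advice
#' rules. The conditional probabilities are authored clinical content, not
#' fitted estimates; see the package vignette for how they were chosen.
#'
#' @return A validated `redeye_kb`.
#' @examples
#' kb <- default_kb()
#' sum(kb$diagnoses$urgent)
#' @export
default_kb <- function() {
  read_kb(system.file("extdata", "redeye-kb.yaml", package = "redeye"))
}

# P(YES | diagnosis) matrix, diagnoses x questions, defaults filled in.
kb_yes_matrix <- function(kb) {
  m <- matrix(NA_real_, nrow = nrow(kb$diagnoses), ncol = nrow(kb$questions),
              dimnames = list(kb$diagnoses$id, kb$questions$id))
  for (i in seq_len(nrow(kb$questions))) {
    p <- rep(kb$questions$yes_default[i], nrow(kb$diagnoses))
    explicit <- kb$questions$yes_prob[[i]]
    p[match(names(explicit), kb$diagnoses$id)] <- explicit
    m[, i] <- p
  }
  m
}

kb_question <- function(kb, id) {
  i <- match(id, kb$questions$id)
  if (is.na(i)) {
    abort(paste0("unknown question id: ", id), class = "redeye_lookup_error")
  }
  kb$questions[i, ]
}

# P(YES | each diagnosis) for one question, defaults filled
question_yes_prob <- function(kb, id) {
  q <- kb_question(kb, id)
  p <- setNames(rep(q$yes_default, nrow(kb$diagnoses)), kb$diagnoses$id)
  explicit <- q$yes_prob[[1]]
  p[names(explicit)] <- explicit
  p
}

#' @export
print.redeye_kb <- function(x, ...) {
  cat("<redeye_kb> ", nrow(x$diagnoses), " diagnoses (",
      sum(x$diagnoses$urgent), " urgent), ",
      nrow(x$questions), " questions (",
      sum(x$questions$opening), " opening), ",
      nrow(x$advice), " advice rules\n", sep = "")
  cat("  settings: theta=", x$settings$theta,
      ", stop_posterior=", x$settings$stop_posterior,
      ", voi_mode=", x$settings$voi_mode, "\n", sep = "")
  invisible(x)
}
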