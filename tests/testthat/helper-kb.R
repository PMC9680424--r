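# KB fixtures are built in code: helpers assemble a raw KB list, write it as
# YAML to a tempfile and load it through the public reader, so every fixture
# also exercises the parse/validate path.

dx <- function(id, name = toupper(id), urgent = FALSE, prior = 1) {
  list(id = id, name = name, urgent = urgent, prior = prior)
}

qq <- function(id, probs, text = paste0("Is ", id, " present?"),
               opening = FALSE, prereq = NULL, redundancy = NULL) {
  q <- list(id = id, text = text, opening = opening, yes_prob = as.list(probs))
  if (!is.null(prereq)) q$prerequisites <- prereq
  if (!is.null(redundancy)) q$redundancy_triggers <- redundancy
  q
}

pair <- function(question, answer) list(question = question, answer = answer)

make_kb <- function(diagnoses, questions, advice = NULL, settings = NULL) {
  raw <- list(diagnoses = diagnoses, questions = questions)
  if (!is.null(advice)) raw$advice <- advice
  if (!is.null(settings)) raw$settings <- settings
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(raw, path)
  read_kb(path)
}

# two diagnoses A, B and a single question with P(YES|A), P(YES|B)
two_dx_kb <- function(pA = 0.8, pB = 0.4, priors = c(1, 1)) {
  make_kb(
    list(dx("A", prior = priors[1]), dx("B", prior = priors[2])),
    list(qq("q1", list(A = pA, B = pB)))
  )
}

# random KB for property tests; probabilities kept off 0/1 so that random
# answer sequences cannot contradict
rand_kb <- function(n_dx, n_q) {
  ids <- sprintf("d%02d", seq_len(n_dx))
  diagnoses <- lapply(seq_len(n_dx), function(i) {
    dx(ids[i], prior = runif(1, 0.2, 2))
  })
  questions <- lapply(seq_len(n_q), function(j) {
    probs <- as.list(setNames(round(runif(n_dx, 0.05, 0.95), 3), ids))
    qq(sprintf("q%02d", j), probs)
  })
  make_kb(diagnoses, questions)
}

# independent oracle: single-pass normalized product of per-question
# likelihoods over the answered set (no sequential machinery)
brute_force_posterior <- function(kb, answers) {
  p <- kb$diagnoses$prior
  names(p) <- kb$diagnoses$id
  for (qid in names(answers)) {
    a <- answers[[qid]]
    if (a == "unknown") next
    i <- match(qid, kb$questions$id)
    py <- rep(kb$questions$yes_default[i], length(p))
    names(py) <- names(p)
    expl <- kb$questions$yes_prob[[i]]
    py[names(expl)] <- expl
    p <- p * (if (a == "yes") py else 1 - py)
  }
  p / sum(p)
}

random_answers <- function(kb, n, include_unknown = TRUE) {
  qids <- sample(kb$questions$id, n)
  pool <- if (include_unknown) c("yes", "no", "unknown") else c("yes", "no")
  setNames(sample(pool, n, replace = TRUE), qids)
}

session_with_answers <- function(kb, answers) {
  s <- new_session(kb)
  for (qid in names(answers)) {
    s <- answer_question(s, qid, answers[[qid]], on_contradiction = "skip")
  }
  s
}
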