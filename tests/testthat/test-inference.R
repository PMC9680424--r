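test_that("init_belief normalizes priors and rejects degenerate ones", {
  expect_equal(init_belief(two_dx_kb())$prob, c(0.5, 0.5))
  expect_equal(init_belief(two_dx_kb(priors = c(3, 1)))$prob, c(0.75, 0.25))
  expect_equal(sum(init_belief(default_kb())$prob), 1, tolerance = 1e-12)

  kb <- two_dx_kb()
  kb$diagnoses$prior <- c(0, 0)
  expect_error(init_belief(kb), class = "redeye_init_error")
})

test_that("single Bayes updates follow the likelihood-ratio arithmetic", {
  kb <- two_dx_kb(pA = 0.8, pB = 0.4)
  b <- init_belief(kb)
  expect_equal(update_posterior(b, kb, "q1", "yes")$prob, c(2 / 3, 1 / 3),
               tolerance = 1e-12)
  # unknown is evidence-free
  expect_equal(update_posterior(b, kb, "q1", "unknown"), b)
  # hard rule-out: zero conditional probability kills the diagnosis on YES
  kb0 <- two_dx_kb(pA = 0, pB = 0.5, priors = c(0.3, 0.7))
  expect_equal(update_posterior(init_belief(kb0), kb0, "q1", "yes")$prob, c(0, 1))
  # ... and ruling out everything is a contradiction
  kb00 <- two_dx_kb(pA = 0, pB = 0)
  expect_error(update_posterior(init_belief(kb00), kb00, "q1", "yes"),
               class = "redeye_contradiction")
})

test_that("sequential updates equal the single-pass product oracle", {
  set.seed(401)
  for (rep in 1:30) {
    kb <- rand_kb(sample(2:15, 1), sample(5:30, 1))
    answers <- random_answers(kb, min(5, nrow(kb$questions)))
    b <- init_belief(kb)
    for (qid in names(answers)) {
      b <- update_posterior(b, kb, qid, answers[[qid]])
    }
    expect_equal(sum(b$prob), 1, tolerance = 1e-9)
    oracle <- brute_force_posterior(kb, answers)
    expect_equal(setNames(b$prob, b$diagnosis), oracle, tolerance = 1e-9)
  }
})

test_that("answer order never changes the final belief", {
  set.seed(402)
  for (rep in 1:15) {
    kb <- rand_kb(sample(3:10, 1), 8)
    answers <- random_answers(kb, 6)
    ref <- session_with_answers(kb, answers)$belief
    for (p in 1:3) {
      perm <- sample(names(answers))
      got <- session_with_answers(kb, setNames(answers[perm], perm))$belief
      expect_equal(got$prob, ref$prob, tolerance = 1e-9)
    }
  }
})

test_that("unknown answers never perturb belief or ranking", {
  set.seed(403)
  kb <- rand_kb(6, 10)
  answers <- random_answers(kb, 4, include_unknown = FALSE)
  b1 <- session_with_answers(kb, answers)$belief
  padded <- c(answers,
              setNames(rep("unknown", 3),
                       setdiff(kb$questions$id, names(answers))[1:3]))
  b2 <- session_with_answers(kb, padded)$belief
  expect_equal(b2$prob, b1$prob, tolerance = 1e-12)
  expect_equal(rank_differential(b2, kb)$diagnosis,
               rank_differential(b1, kb)$diagnosis)
})

test_that("YES to a more-likely-under-d1 question never lowers d1:d2 odds", {
  set.seed(404)
  for (rep in 1:20) {
    kb <- rand_kb(5, 6)
    b <- init_belief(kb)
    pre <- session_with_answers(kb, random_answers(kb, 2))$belief
    qid <- sample(kb$questions$id, 1)
    py <- kb$questions$yes_prob[[match(qid, kb$questions$id)]]
    ord <- order(py, decreasing = TRUE)
    d1 <- names(py)[ord[1]]
    d2 <- names(py)[ord[length(py)]]
    post <- update_posterior(pre, kb, qid, "yes")
    ratio <- function(bel) {
      v <- setNames(bel$prob, bel$diagnosis)
      v[[d1]] / v[[d2]]
    }
    expect_gte(ratio(post), ratio(pre) - 1e-12)
  }
})

test_that("rank_differential sorts, breaks ties by KB order, keeps urgent visible", {
  kb <- make_kb(
    list(dx("a", prior = 0.5), dx("b", prior = 0.3), dx("c", prior = 0.2)),
    list(qq("q1", list(default = 0.5)))
  )
  d <- rank_differential(init_belief(kb), kb)
  expect_equal(d$diagnosis, c("a", "b", "c"))
  expect_equal(d$rank, 1:3)

  kb_tie <- make_kb(
    list(dx("first", prior = 0.4), dx("second", prior = 0.4), dx("rest", prior = 0.2)),
    list(qq("q1", list(default = 0.5)))
  )
  expect_equal(rank_differential(init_belief(kb_tie), kb_tie)$diagnosis[1:2],
               c("first", "second"))

  # a low-posterior urgent diagnosis survives any display cutoff
  kb_urg <- make_kb(
    list(dx("common", prior = 0.99), dx("mid", prior = 0.006),
         dx("rare_urgent", urgent = TRUE, prior = 0.004)),
    list(qq("q1", list(default = 0.5)))
  )
  d <- rank_differential(init_belief(kb_urg), kb_urg, top = 1)
  expect_true("rare_urgent" %in% d$diagnosis)
  expect_false("mid" %in% d$diagnosis)

  # numeric and visual scores
  expect_equal(d$score[d$diagnosis == "common"], 99.0)
  expect_equal(d$bar[d$diagnosis == "common"], 10L)
})

test_that("evidence classification matches the relative-posterior-shift oracle", {
  kb <- make_kb(
    list(dx("ulcer"), dx("plain")),
    list(qq("spot", list(ulcer = 0.9, plain = 0.2)),
         qq("ache", list(ulcer = 0.8, plain = 0.1)))
  )
  s <- new_session(kb)
  expect_equal(nrow(evidence_for(s, "ulcer")), 0)

  s <- answer_question(s, "spot", "yes")
  s <- answer_question(s, "ache", "no")
  ev <- evidence_for(s, "ulcer")
  expect_equal(ev$direction[ev$question == "spot"], "support")
  expect_equal(ev$direction[ev$question == "ache"], "refute")

  # oracle: direction agrees with whether the update raised the diagnosis's
  # posterior share
  for (i in seq_len(nrow(ev))) {
    b <- init_belief(kb)
    post <- update_posterior(b, kb, ev$question[i], ev$answer[i])
    shift <- post$prob[post$diagnosis == "ulcer"] - b$prob[b$diagnosis == "ulcer"]
    expect_equal(ev$direction[i], if (shift > 0) "support" else "refute")
  }

  expect_error(evidence_for(s, "nope"), class = "redeye_lookup_error")
})

test_that("stopping rule fires on dominance or exhaustion, flags no-discrimination", {
  kb <- make_kb(
    list(dx("big", prior = 0.9), dx("small", prior = 0.05), dx("tiny", prior = 0.05)),
    list(qq("q1", list(default = 0.5))),
    settings = list(theta = 5, stop_posterior = 0.5)
  )
  st <- check_stop(new_session(kb))
  expect_true(st$stop)
  expect_equal(st$reason, "dominance")

  # everything unknown: bank exhausted with the belief still at the prior
  kb2 <- two_dx_kb()
  s <- session_with_answers(kb2, c(q1 = "unknown"))
  st <- check_stop(s)
  expect_true(st$stop)
  expect_equal(st$reason, "exhausted")
  expect_true(st$low_confidence)

  # close race with questions remaining: continue
  kb3 <- make_kb(
    list(dx("a", prior = 0.4), dx("b", prior = 0.35), dx("c", prior = 0.25)),
    list(qq("q1", list(default = 0.5)), qq("q2", list(default = 0.5))),
    settings = list(theta = 5, stop_posterior = 0.5)
  )
  expect_false(check_stop(new_session(kb3))$stop)
})
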