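test_that("a corneal-ulcer presentation tops the differential and triggers advice", {
  kb <- default_kb()
  s <- run_interview(kb,
                     answers = c(stain = "yes", opacity = "yes", lens = "yes"),
                     output = nullfile())
  diff <- rank_differential(s$belief, kb)
  expect_equal(diff$diagnosis[1], "corneal_ulcer")
  msgs <- kb$advice$message[match(s$advice_emitted, kb$advice$id)]
  expect_true(any(grepl("rule out a corneal ulcer", msgs)))
})

test_that("advice fires mid-interview, at most once, when its condition holds", {
  kb <- default_kb()
  s <- new_session(kb)
  s <- answer_question(s, "stain", "yes")
  expect_length(attr(s, "new_advice"), 0)
  s <- answer_question(s, "opacity", "yes")
  expect_true(grepl("corneal ulcer", attr(s, "new_advice")))
  s <- answer_question(s, "lens", "yes")
  expect_length(attr(s, "new_advice"), 0)  # no re-fire
  expect_equal(sum(s$advice_emitted == "ulcer_rule_out"), 1)
})

test_that("an all-unknown interview exits low-confidence", {
  kb <- default_kb()
  s <- run_interview(kb, answers = character(0), output = nullfile())
  expect_true(s$stopped)
  expect_equal(s$stop_reason, "exhausted")
  expect_true(s$low_confidence)
  # the differential is just the prior ranking
  expect_equal(rank_differential(s$belief, kb)$diagnosis,
               rank_differential(init_belief(kb), kb)$diagnosis)
})

test_that("interactive input handles quit and the three-strikes rule", {
  kb <- default_kb()
  s <- run_interview(kb, input = "quit", output = nullfile())
  expect_equal(s$stop_reason, "user")
  expect_equal(nrow(s$answered), 0)

  # three unparseable lines are recorded as unknown
  s <- run_interview(kb, input = c("banana", "banana", "banana"),
                     output = nullfile())
  expect_equal(s$answered$answer[1], "unknown")
})

test_that("batch and interactive paths give identical differentials", {
  set.seed(601)
  kb <- default_kb()
  cases <- simulate_cases(kb, 10, unknown_rate = 0.3, noise_rate = 0.1, seed = 9)
  res <- batch_diagnose(cases, kb)
  qids <- intersect(kb$questions$id, names(cases))
  for (i in seq_len(nrow(cases))) {
    answers <- setNames(unlist(cases[i, qids]), qids)
    s <- session_with_answers(kb, answers)
    expect_equal(res$differential[[i]]$posterior,
                 rank_differential(s$belief, kb)$posterior,
                 tolerance = 1e-12)
    expect_equal(res$differential[[i]]$diagnosis,
                 rank_differential(s$belief, kb)$diagnosis)
  }
})

test_that("batch results are deterministic and duplicate cases agree", {
  kb <- default_kb()
  case <- tibble::tibble(case_id = c("a", "b"),
                         pain = "yes", stain = "yes", fbs = "yes")
  res <- batch_diagnose(case, kb)
  expect_equal(res$differential[[1]], res$differential[[2]])
  expect_equal(res$top1[1], res$top1[2])
})

test_that("unmapped case columns are rejected with the offenders listed", {
  kb <- default_kb()
  bad <- tibble::tibble(case_id = "x", not_a_question = "yes")
  expect_error(batch_diagnose(bad, kb), regexp = "not_a_question",
               class = "redeye_column_error")
})

test_that("an empty case returns the prior ranking, flagged low-confidence", {
  kb <- default_kb()
  res <- batch_diagnose(tibble::tibble(case_id = "e", pain = "unknown"), kb)
  expect_true(res$low_confidence[1])
  expect_equal(res$differential[[1]]$diagnosis,
               rank_differential(init_belief(kb), kb)$diagnosis)
})

test_that("raised-pressure findings flip the top diagnosis to angle closure", {
  kb <- default_kb()
  referrer <- tibble::tibble(case_id = "c6", iop = "yes", pupil = "yes")
  ophtho <- tibble::tibble(case_id = "c6", iop = "no", pupil = "no")
  expect_equal(batch_diagnose(referrer, kb)$top1, "acute_acg")
  expect_equal(batch_diagnose(ophtho, kb)$top1, "keratitis")
})

test_that("withdrawing the staining finding brings scleritis into the top two", {
  kb <- default_kb()
  referrer <- tibble::tibble(case_id = "c5", fbs = "yes", pain = "yes",
                             stain = "yes")
  res_ref <- batch_diagnose(referrer, kb)
  expect_equal(res_ref$top1, "keratitis")
  expect_false("scleritis" %in% c(res_ref$top1, res_ref$top2))

  rerun <- perturb_answers(referrer, c(stain = "no"))
  res_new <- batch_diagnose(rerun, kb)
  expect_equal(res_new$top1, "keratitis")
  expect_equal(res_new$top2, "scleritis")
})

test_that("contradictory answers are skipped with a warning at the front-end", {
  kb <- make_kb(list(dx("A"), dx("B")),
                list(qq("q1", list(A = 0, B = 0)),
                     qq("q2", list(A = 0.9, B = 0.1))))
  expect_warning(
    res <- batch_diagnose(tibble::tibble(case_id = "x", q1 = "yes", q2 = "yes"), kb),
    regexp = "contradictory"
  )
  # the q2 update still applied
  expect_equal(res$top1, "A")
})

test_that("the belief trajectory records one snapshot per answer", {
  kb <- default_kb()
  s <- session_with_answers(kb, c(pain = "yes", stain = "no"))
  traj <- belief_trajectory(s)
  expect_equal(unique(traj$step), 0:2)
  expect_equal(nrow(traj), 3 * nrow(kb$diagnoses))
  # step 0 is the prior
  expect_equal(traj$posterior[traj$step == 0], init_belief(kb)$prob)
  expect_equal(tidy(s), traj)
})
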