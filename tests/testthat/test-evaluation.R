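test_that("case CSVs parse with blanks as unknown and labels normalized", {
  kb <- default_kb()
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "case_id,pain,stain,referrer_dx,gold_dx",
    "c1,yes,,keratitis,keratitis",
    "c2,no,no,,iritis",
    "c3,yes,yes,keratitis,pingueculitis"
  ), path)
  expect_warning(cases <- read_cases(path, kb), regexp = "pingueculitis")
  expect_equal(cases$stain[1], "unknown")    # blank cell
  expect_equal(cases$referrer_dx[2], "none") # no diagnosis attempted
  expect_equal(cases$gold_dx[3], "other")    # outside the ontology

  bad <- tempfile(fileext = ".csv")
  writeLines(c("case_id,pain,gold_dx", "c1,yes,"), bad)
  expect_error(read_cases(bad, kb), regexp = "c1", class = "redeye_case_error")
})

test_that("top-k scoring counts gold-in-top-k and is monotone in k", {
  kb <- default_kb()
  set.seed(701)
  cases <- simulate_cases(kb, 60, seed = 17)
  res <- batch_diagnose(cases, kb)
  acc <- topk_accuracy(res, cases)
  expect_equal(acc$k, 1:3)
  expect_true(all(diff(acc$correct) >= 0))
  expect_true(all(acc$accuracy >= 0 & acc$accuracy <= 100))

  # hand-check k=1 against the top1 column
  joined <- merge(res[, c("case_id", "top1")], cases[, c("case_id", "gold_dx")])
  expect_equal(acc$correct[1], sum(joined$top1 == joined$gold_dx))

  # an "other" gold label never scores correct
  cases2 <- cases
  cases2$gold_dx <- "other"
  expect_equal(topk_accuracy(res, cases2, k = 3)$correct, 0)

  expect_error(topk_accuracy(res, cases[-1, ]),
               class = "redeye_alignment_error")
})

test_that("exact binomial CIs match the reference implementation", {
  expect_equal(clopper_pearson(0, 10)[["lower"]], 0)
  expect_equal(clopper_pearson(10, 10)[["upper"]], 1)

  # independent oracle: stats::binom.test over the full small-n grid
  for (n in 1:40) {
    for (x in 0:n) {
      got <- clopper_pearson(x, n)
      ref <- binom.test(x, n)$conf.int
      expect_equal(unname(got), as.numeric(ref), tolerance = 1e-6)
      expect_lte(got[["lower"]], x / n + 1e-12)
      expect_gte(got[["upper"]], x / n - 1e-12)
    }
    # lower bound nondecreasing in x at fixed n
    lowers <- vapply(0:n, function(x) clopper_pearson(x, n)[["lower"]],
                     numeric(1))
    expect_true(all(diff(lowers) >= 0))
  }

  expect_error(clopper_pearson(5, 4), class = "redeye_argument_error")
  expect_error(clopper_pearson(-1, 4), class = "redeye_argument_error")
  expect_error(clopper_pearson(2, 4, alpha = 1.2),
               class = "redeye_argument_error")
})

test_that("urgency metrics classify by the top diagnosis with exact CIs", {
  kb <- default_kb()
  # separable toy set: urgent gold cases that the engine calls urgent
  cases <- tibble::tibble(
    case_id = c("u1", "u2", "n1", "n2"),
    iop = c("yes", "yes", "no", "no"),
    pupil = c("yes", "yes", "no", "no"),
    discharge = c("no", "no", "yes", "yes"),
    gold_dx = c("acute_acg", "acute_acg", "conjunctivitis", "conjunctivitis"),
    referrer_dx = "none"
  )
  res <- batch_diagnose(cases, kb)
  um <- urgency_metrics(res, cases, kb)
  expect_equal(um$metrics$percent, c(100, 100))
  expect_equal(sum(um$confusion$count), 4)
  expect_equal(um$confusion$count[um$confusion$gold == "urgent" &
                                    um$confusion$predicted == "urgent"], 2)

  # no urgent gold cases: sensitivity undefined, not zero
  nonurg <- cases[3:4, ]
  um2 <- urgency_metrics(batch_diagnose(nonurg, kb), nonurg, kb)
  expect_true(is.na(um2$metrics$percent[um2$metrics$metric == "sensitivity"]))
})

test_that("evaluate_cases assembles concordance, accuracies and urgency", {
  kb <- default_kb()
  cases <- simulate_cases(kb, 40, unknown_rate = 0, noise_rate = 0, seed = 23)
  cases$referrer_dx <- cases$gold_dx  # a perfect referrer
  ev <- evaluate_cases(cases, kb)
  expect_s3_class(ev, "redeye_eval")
  expect_equal(sum(ev$concordance$n), 40)
  expect_equal(ev$overall$accuracy[ev$overall$measure == "referrer"], 100)
  expect_true(all(diff(ev$overall$correct[-1]) >= 0))  # top1 <= top2 <= top3

  g <- glance(ev)
  expect_equal(g$n, 40)
  expect_true(all(c("sensitivity", "specificity") %in% names(g)))
  td <- tidy(ev)
  expect_equal(sum(td$correct[td$measure == "top1"]),
               ev$overall$correct[ev$overall$measure == "top1"])
})

test_that("evaluation reports export to JSON and round-trip their counts", {
  kb <- default_kb()
  counts <- readr::read_csv(
    system.file("extdata", "concordance-counts.csv", package = "redeye"),
    show_col_types = FALSE
  )
  ev <- concordance_eval(counts, kb)
  path <- tempfile(fileext = ".json")
  eval_to_json(ev, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$concordance$n, counts$n)
  expect_equal(back$concordance$top3, counts$top3)
  expect_equal(back$overall$accuracy, ev$overall$accuracy)
})

test_that("malformed concordance tables are rejected", {
  kb <- default_kb()
  good <- tibble::tibble(diagnosis = "keratitis", n = 5, referrer = 3,
                         top1 = 2, top2 = 3, top3 = 4)
  expect_s3_class(concordance_eval(good, kb), "redeye_eval")
  expect_error(concordance_eval(good[, -2], kb), class = "redeye_case_error")
  expect_error(concordance_eval(good[0, ], kb), class = "redeye_case_error")
  bad <- good
  bad$top1 <- 4  # violates top1 <= top2
  expect_error(concordance_eval(bad, kb), class = "redeye_case_error")
  bad2 <- good
  bad2$referrer <- 9  # exceeds n
  expect_error(concordance_eval(bad2, kb), class = "redeye_case_error")
})
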