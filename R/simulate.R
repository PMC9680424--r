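#' Simulate synthetic patient questionnaires
#'
#' Generates answer vectors with exactly the statistical structure the
#' engine assumes: a gold diagnosis is drawn from `prevalence`, then each
#' question's answer is Bernoulli(P(YES | gold diagnosis)) — conditionally
#' independent given the diagnosis — optionally flipped with probability
#' `noise_rate` (a referrer mis-eliciting or mis-recording a finding) and
#' blanked to "unknown" with probability `unknown_rate` (an undocumented
#' response). Because the generator shares the engine's independence
#' assumption, recovery results exercise the software, not the clinical
#' validity of the KB.
#'
#' `referrer_dx` is left as `"none"`: synthetic cases test the algorithm,
#' not referrers.
#'
#' @param kb A `redeye_kb`.
#' @param n Number of cases.
#' @param prevalence `"priors"` (KB priors; default), `"ed-mix"` (the
#'   emergency-department case mix of the published 57-patient evaluation),
#'   or a named nonnegative weight vector over diagnosis ids.
#' @param unknown_rate Probability an answer is blanked to "unknown".
#'   Default 0.3: in referral practice a large share of checklist findings
#'   go undocumented.
#' @param noise_rate Probability a YES/NO answer is flipped before
#'   blanking. Default 0.05, the order of referrer/specialist disagreement
#'   seen on individual findings.
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output. `NULL` uses the current RNG state.
#' @return A case tibble: `case_id`, one column per KB question, and
#'   `referrer_dx`, `gold_dx`.
#' @examples
#' simulate_cases(default_kb(), n = 5, seed = 1)
#' @export
simulate_cases <- function(kb, n, prevalence = "priors",
                           unknown_rate = 0.3, noise_rate = 0.05,
                           seed = NULL) {
  stopifnot(inherits(kb, "redeye_kb"))
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    abort("n must be a positive integer", class = "redeye_argument_error")
  }
  for (r in c(unknown_rate = unknown_rate, noise_rate = noise_rate)) {
    if (!is.numeric(r) || is.na(r) || r < 0 || r > 1) {
      abort("rates must lie in [0, 1]", class = "redeye_argument_error")
    }
  }
  w <- resolve_prevalence(prevalence, kb)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }

  qs <- kb$questions$id
  yes_mat <- kb_yes_matrix(kb)
  gold <- sample(kb$diagnoses$id, n, replace = TRUE, prob = w)

  ans <- matrix("", nrow = n, ncol = length(qs), dimnames = list(NULL, qs))
  for (q in qs) {
    p <- yes_mat[gold, q]
    yes <- runif(n) < p
    flip <- runif(n) < noise_rate
    yes <- xor(yes, flip)
    a <- ifelse(yes, "yes", "no")
    a[runif(n) < unknown_rate] <- "unknown"
    ans[, q] <- a
  }

  out <- as_tibble(as.data.frame(ans, stringsAsFactors = FALSE))
  out$case_id <- sprintf("case_%05d", seq_len(n))
  out$referrer_dx <- "none"
  out$gold_dx <- gold
  relocate(out, "case_id")
}

resolve_prevalence <- function(prevalence, kb) {
  ids <- kb$diagnoses$id
  if (is.character(prevalence) && length(prevalence) == 1) {
    w <- switch(prevalence,
      "priors" = setNames(kb$diagnoses$prior, ids),
      "ed-mix" = ed_mix_prevalence(kb),
      abort(paste0("unknown prevalence preset: ", prevalence),
            class = "redeye_argument_error")
    )
  } else {
    if (is.null(names(prevalence)) || !all(names(prevalence) %in% ids)) {
      abort("prevalence weights must be named by KB diagnosis ids",
            class = "redeye_argument_error")
    }
    w <- setNames(rep(0, length(ids)), ids)
    w[names(prevalence)] <- as.numeric(prevalence)
  }
  if (any(is.na(w) | w < 0) || sum(w) <= 0) {
    abort("prevalence weights must be nonnegative and not all zero",
          class = "redeye_argument_error")
  }
  unname(w[ids])
}

#' Emergency-department case-mix weights
#'
#' The gold-standard case mix of the published 57-patient
#' emergency-department evaluation (54 classifiable cases): heavy in
#' keratitis/corneal abrasion, iritis and corneal ulcer, with several
#' conditions unrepresented. Returned as sampling weights over the KB's
#' diagnosis ids for [simulate_cases()].
#'
#' @param kb A `redeye_kb` (weights are matched to its diagnosis ids;
#'   diagnoses outside the mix get weight 0).
#' @return Named numeric vector of weights.
#' @export
ed_mix_prevalence <- function(kb) {
  stopifnot(inherits(kb, "redeye_kb"))
  mix <- c(eczema = 1, tearduct = 0, lid_abnormality = 0, blepharitis = 0,
           dry_eye = 2, subconj_blood = 1, avm = 0, conjunctivitis = 4,
           episcleritis = 0, scleritis = 4, keratitis = 16, corneal_ulcer = 11,
           acute_acg = 1, iritis = 13, endophthalmitis = 1)
  w <- setNames(rep(0, nrow(kb$diagnoses)), kb$diagnoses$id)
  common <- intersect(names(mix), names(w))
  w[common] <- mix[common]
  w
}

#' Apply answer edits to a case
#'
#' Returns a modified copy of one case row with the given answers replaced —
#' the "re-run the algorithm with the corrected finding" operation used when
#' specialist findings disagree with referrer findings. The original is
#' untouched; an empty edit set returns an identical case.
#'
#' @param case A one-row case tibble.
#' @param edits Named character vector (question id -> new answer), or a
#'   data frame with columns `question`, `answer`.
#' @return The edited one-row case tibble.
#' @examples
#' kb <- default_kb()
#' case <- simulate_cases(kb, 1, seed = 1)
#' perturb_answers(case, c(stain = "no"))
#' @export
perturb_answers <- function(case, edits) {
  stopifnot(is.data.frame(case), nrow(case) == 1)
  if (is.data.frame(edits)) {
    edits <- setNames(as.character(edits$answer), edits$question)
  }
  if (length(edits) == 0) return(case)
  bad <- setdiff(names(edits), names(case))
  if (length(bad)) {
    abort(paste0("edit(s) reference unknown question column(s): ",
                 paste(bad, collapse = ", ")),
          class = "redeye_column_error")
  }
  for (q in names(edits)) {
    a <- parse_answer(edits[[q]])
    if (is.na(a)) {
      abort(paste0("unparseable edited answer for '", q, "'"),
            class = "redeye_answer_error")
    }
    case[[q]] <- a
  }
  case
}

#' Write a case table to CSV
#'
#' Deterministic column order (case_id, questions in KB order if a KB is
#' given, then referrer_dx, gold_dx), so the same simulated batch always
#' produces a byte-identical file.
#'
#' @param cases A case tibble.
#' @param path Output path.
#' @param kb Optional `redeye_kb` fixing the question column order.
#' @return `path`, invisibly.
#' @export
write_cases <- function(cases, path, kb = NULL) {
  cases <- as_tibble(cases)
  if (!is.null(kb)) {
    qcols <- kb$questions$id[kb$questions$id %in% names(cases)]
    cases <- cases[, c("case_id", qcols,
                       intersect(c("referrer_dx", "gold_dx"), names(cases)))]
  }
  readr::write_csv(cases, path, progress = FALSE)
  invisible(path)
}
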