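#' Read a case table from CSV
#'
#' The case CSV dialect: one row per patient; a `case_id` column; one column
#' per question id (cells `yes`/`no`/`unknown`, blank meaning "unknown" — an
#' undocumented response carries no evidence); a `gold_dx` column
#' (required); an optional `referrer_dx` column, blank meaning no diagnosis
#' was attempted (scored incorrect). Diagnosis labels outside the KB (and
#' outside `"other"`/`"none"`) are mapped to `"other"` with a warning — a
#' gold diagnosis the KB cannot express is always scored as an algorithm
#' miss.
#'
#' @param path CSV file path.
#' @param kb A `redeye_kb` used to check question columns and diagnosis
#'   labels.
#' @return A tibble of cases ready for [batch_diagnose()] /
#'   [evaluate_cases()].
#' @export
read_cases <- function(path, kb) {
  stopifnot(inherits(kb, "redeye_kb"))
  cases <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  if (!("gold_dx" %in% names(cases))) {
    abort("case file has no gold_dx column", class = "redeye_case_error")
  }
  if (!("case_id" %in% names(cases))) {
    cases$case_id <- sprintf("case_%03d", seq_len(nrow(cases)))
  }
  missing_gold <- which(is.na(cases$gold_dx) | !nzchar(trimws(cases$gold_dx)))
  if (length(missing_gold)) {
    abort(paste0("missing gold_dx for case(s): ",
                 paste(cases$case_id[missing_gold], collapse = ", ")),
          class = "redeye_case_error")
  }
  qcols <- setdiff(names(cases), c("case_id", "referrer_dx", "gold_dx"))
  unknown_cols <- setdiff(qcols, kb$questions$id)
  if (length(unknown_cols)) {
    abort(paste0("case columns do not map onto KB question ids: ",
                 paste(unknown_cols, collapse = ", ")),
          class = "redeye_column_error")
  }
  for (qc in qcols) {
    parsed <- parse_answer(cases[[qc]])
    parsed[is.na(parsed)] <- "unknown"
    cases[[qc]] <- parsed
  }
  cases$gold_dx <- normalize_dx(cases$gold_dx, kb, allow_none = FALSE)
  if ("referrer_dx" %in% names(cases)) {
    cases$referrer_dx <- normalize_dx(cases$referrer_dx, kb, allow_none = TRUE)
  } else {
    cases$referrer_dx <- "none"
  }
  cases
}

# map free-text diagnosis labels onto KB ids / "other" / "none"
normalize_dx <- function(x, kb, allow_none = TRUE) {
  x <- tolower(trimws(x))
  x[is.na(x) | !nzchar(x)] <- if (allow_none) "none" else NA_character_
  known <- c(kb$diagnoses$id, "other", if (allow_none) "none")
  bad <- setdiff(unique(x), known)
  if (length(bad)) {
    warn(paste0("diagnosis label(s) outside the KB mapped to 'other': ",
                paste(bad, collapse = ", ")))
    x[x %in% bad] <- "other"
  }
  x
}

#' Top-k accuracy of batch results against gold-standard diagnoses
#'
#' A case is correct at level k iff its gold diagnosis appears among the
#' first k entries of the ranked differential; `"other"` gold labels
#' (conditions outside the KB's ontology) can never match and are scored
#' incorrect.
#'
#' @param results Output of [batch_diagnose()].
#' @param cases The matching case tibble (with `gold_dx`).
#' @param k Vector of cutoffs (default `1:3`).
#' @return A tibble with columns `k`, `correct`, `n`, `accuracy` (percent,
#'   half-up to one decimal).
#' @export
topk_accuracy <- function(results, cases, k = 1:3) {
  joined <- align_results(results, cases)
  list_rbind(map(k, function(kk) {
    hits <- map_lgl(seq_len(nrow(joined)), function(i) {
      topk <- joined$differential[[i]]$diagnosis[seq_len(kk)]
      joined$gold_dx[i] %in% topk
    })
    tibble(k = kk, correct = sum(hits), n = nrow(joined),
           accuracy = pct1(sum(hits) / nrow(joined)))
  }))
}

align_results <- function(results, cases) {
  stopifnot(is.data.frame(results), is.data.frame(cases))
  if (!setequal(results$case_id, cases$case_id) ||
      anyDuplicated(results$case_id) || anyDuplicated(cases$case_id)) {
    abort("results and cases do not align by case_id",
          class = "redeye_alignment_error")
  }
  left_join(results, as_tibble(cases)[, intersect(names(cases),
                                                  c("case_id", "referrer_dx", "gold_dx"))],
            by = "case_id")
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' The exact two-sided interval from beta-distribution quantiles:
#' lower = qbeta(alpha/2; x, n - x + 1) (0 when x = 0),
#' upper = qbeta(1 - alpha/2; x + 1, n - x) (1 when x = n).
#'
#' @param x Number of successes (0 <= x <= n).
#' @param n Number of trials (>= 1).
#' @param alpha Two-sided error level in (0, 1); 0.05 gives a 95% CI.
#' @return Named numeric vector `c(lower, upper)` on the probability scale.
#' @examples
#' clopper_pearson(20, 26)  # rounds to [56%, 91%]
#' @export
clopper_pearson <- function(x, n, alpha = 0.05) {
  if (!is.numeric(x) || !is.numeric(n) || length(x) != 1 || length(n) != 1 ||
      is.na(x) || is.na(n) || n < 1 || x < 0 || x > n ||
      x != round(x) || n != round(n)) {
    abort("clopper_pearson requires integers 0 <= x <= n, n >= 1",
          class = "redeye_argument_error")
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    abort("alpha must lie strictly between 0 and 1",
          class = "redeye_argument_error")
  }
  lower <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

# sensitivity/specificity style proportion with CI, report-ready rounding:
# percent half-up to 1 decimal; CI bounds half-up to whole percent
prop_with_ci <- function(x, n, alpha = 0.05) {
  if (n == 0) {
    return(tibble(x = x, n = n, percent = NA_real_,
                  ci_lower = NA_real_, ci_upper = NA_real_))
  }
  ci <- clopper_pearson(x, n, alpha)
  tibble(x = x, n = n, percent = pct1(x / n),
         ci_lower = round_half_up(100 * ci[["lower"]]),
         ci_upper = round_half_up(100 * ci[["upper"]]))
}

#' Urgency triage metrics
#'
#' Classifies each case as urgent iff its *top* diagnosis carries the KB's
#' urgent flag, and compares against gold urgency (gold diagnosis flagged
#' urgent; `"other"` counts non-urgent). Reports the 2x2 confusion matrix
#' and sensitivity/specificity with exact Clopper-Pearson CIs (percentages
#' half-up to one decimal, CI bounds to whole percent). A zero denominator
#' yields `NA` (undefined), never 0. Set `k > 1` to explore classifying a
#' case urgent when any of the top k diagnoses is urgent; the headline
#' metrics use `k = 1`.
#'
#' @param results Output of [batch_diagnose()].
#' @param cases The matching case tibble.
#' @param kb The `redeye_kb` supplying urgency flags.
#' @param k Top-k cutoff for the urgent call (default 1).
#' @param alpha CI error level (default 0.05).
#' @return A list with `confusion` (tibble) and `metrics` (tibble with one
#'   row per metric).
#' @export
urgency_metrics <- function(results, cases, kb, k = 1, alpha = 0.05) {
  stopifnot(inherits(kb, "redeye_kb"))
  joined <- align_results(results, cases)
  urgent_ids <- kb$diagnoses$id[kb$diagnoses$urgent]
  pred_urgent <- map_lgl(seq_len(nrow(joined)), function(i) {
    any(joined$differential[[i]]$diagnosis[seq_len(k)] %in% urgent_ids)
  })
  gold_urgent <- joined$gold_dx %in% urgent_ids
  confusion <- tibble(
    gold      = rep(c("urgent", "non-urgent"), each = 2),
    predicted = rep(c("urgent", "non-urgent"), times = 2),
    count     = c(sum(gold_urgent & pred_urgent),
                  sum(gold_urgent & !pred_urgent),
                  sum(!gold_urgent & pred_urgent),
                  sum(!gold_urgent & !pred_urgent))
  )
  metrics <- bind_rows(
    mutate(prop_with_ci(sum(gold_urgent & pred_urgent), sum(gold_urgent), alpha),
           metric = "sensitivity"),
    mutate(prop_with_ci(sum(!gold_urgent & !pred_urgent), sum(!gold_urgent), alpha),
           metric = "specificity")
  )
  list(confusion = confusion,
       metrics = relocate(metrics, "metric"))
}

#' Evaluate the engine on a case table
#'
#' The full study-style evaluation: runs [batch_diagnose()], then computes
#' per-cluster concordance counts (referrer and algorithm top-1/2/3 against
#' the gold standard), overall and urgent-subset accuracies, and the
#' urgency confusion metrics. A referrer who attempted no diagnosis
#' (`"none"`) is scored incorrect.
#'
#' @param cases A case tibble from [read_cases()] (or built in code).
#' @param kb A `redeye_kb`.
#' @param alpha CI error level.
#' @return A `redeye_eval` object; see [tidy.redeye_eval()],
#'   [glance.redeye_eval()], [autoplot.redeye_eval()].
#' @export
evaluate_cases <- function(cases, kb, alpha = 0.05) {
  stopifnot(inherits(kb, "redeye_kb"))
  cases <- as_tibble(cases)
  if (!("referrer_dx" %in% names(cases))) cases$referrer_dx <- "none"
  results <- batch_diagnose(cases, kb)
  joined <- align_results(results, cases)

  hit <- function(i, k) joined$gold_dx[i] %in% joined$differential[[i]]$diagnosis[seq_len(k)]
  idx <- seq_len(nrow(joined))
  joined$ref_ok  <- joined$referrer_dx == joined$gold_dx & joined$gold_dx != "other"
  joined$top1_ok <- map_lgl(idx, hit, k = 1)
  joined$top2_ok <- map_lgl(idx, hit, k = 2)
  joined$top3_ok <- map_lgl(idx, hit, k = 3)
  counts <- joined |>
    group_by(diagnosis = .data$gold_dx) |>
    summarise(n = dplyr::n(), referrer = sum(.data$ref_ok),
              top1 = sum(.data$top1_ok), top2 = sum(.data$top2_ok),
              top3 = sum(.data$top3_ok), .groups = "drop")

  new_eval(
    concordance = order_clusters(counts, kb),
    kb = kb,
    urgency = urgency_metrics(results, cases, kb, alpha = alpha),
    alpha = alpha
  )
}

#' Evaluate from a concordance-count table
#'
#' Accepts per-cluster concordance counts directly — one row per
#' gold-standard diagnosis cluster with columns `diagnosis`, `n`,
#' `referrer`, `top1`, `top2`, `top3` — and computes the same accuracy
#' summaries as [evaluate_cases()] without raw cases. This is how published
#' count tables are re-analyzed; the shipped fixture
#' `system.file("extdata", "concordance-counts.csv", package = "redeye")`
#' holds the per-cluster counts from the published 57-patient
#' emergency-department evaluation of this approach. Case-level urgency
#' sensitivity/specificity need raw cases and are not computed here (use
#' [clopper_pearson()] on the urgent-call counts directly).
#'
#' @param counts Data frame of per-cluster counts (diagnosis `"other"`
#'   allowed).
#' @param kb A `redeye_kb` supplying urgency flags.
#' @param alpha CI error level.
#' @return A `redeye_eval` object (without urgency confusion metrics).
#' @examples
#' counts <- readr::read_csv(
#'   system.file("extdata", "concordance-counts.csv", package = "redeye"),
#'   show_col_types = FALSE)
#' glance(concordance_eval(counts, default_kb()))
#' @export
concordance_eval <- function(counts, kb, alpha = 0.05) {
  stopifnot(is.data.frame(counts), inherits(kb, "redeye_kb"))
  counts <- as_tibble(counts)
  need <- c("diagnosis", "n", "referrer", "top1", "top2", "top3")
  missing_cols <- setdiff(need, names(counts))
  if (length(missing_cols)) {
    abort(paste0("concordance table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "redeye_case_error")
  }
  if (nrow(counts) == 0) {
    abort("concordance table is empty", class = "redeye_case_error")
  }
  counts$diagnosis <- normalize_dx(counts$diagnosis, kb, allow_none = FALSE)
  for (col in c("referrer", "top1", "top2", "top3")) {
    if (any(counts[[col]] > counts$n | counts[[col]] < 0)) {
      abort(paste0("count column '", col, "' out of range [0, n]"),
            class = "redeye_case_error")
    }
  }
  if (any(counts$top1 > counts$top2 | counts$top2 > counts$top3)) {
    abort("per-cluster counts must satisfy top1 <= top2 <= top3",
          class = "redeye_case_error")
  }
  new_eval(concordance = order_clusters(counts, kb), kb = kb,
           urgency = NULL, alpha = alpha)
}

# cluster rows in KB declaration order, "other" last
order_clusters <- function(counts, kb) {
  ord <- match(counts$diagnosis, c(kb$diagnoses$id, "other"))
  counts[order(ord), ]
}

new_eval <- function(concordance, kb, urgency, alpha) {
  urgent_ids <- kb$diagnoses$id[kb$diagnoses$urgent]
  sum_over <- function(rows) {
    tot <- summarise(rows, n = sum(.data$n), referrer = sum(.data$referrer),
                     top1 = sum(.data$top1), top2 = sum(.data$top2),
                     top3 = sum(.data$top3))
    acc <- map_dbl(c("referrer", "top1", "top2", "top3"),
                   function(col) if (tot$n > 0) pct1(tot[[col]] / tot$n) else NA_real_)
    tibble(measure = c("referrer", "top1", "top2", "top3"),
           correct = c(tot$referrer, tot$top1, tot$top2, tot$top3),
           n = tot$n, accuracy = acc)
  }
  structure(
    list(
      concordance = concordance,
      overall = sum_over(concordance),
      urgent = sum_over(filter(concordance, .data$diagnosis %in% urgent_ids)),
      non_urgent = sum_over(filter(concordance, !(.data$diagnosis %in% urgent_ids))),
      urgency = urgency,
      alpha = alpha
    ),
    class = "redeye_eval"
  )
}

#' @export
print.redeye_eval <- function(x, ...) {
  cat("<redeye_eval> ", sum(x$concordance$n), " cases, ",
      nrow(x$concordance), " gold clusters\n", sep = "")
  cat("\nPer-cluster concordance (correct/n):\n")
  tab <- mutate(x$concordance,
                referrer = paste0(.data$referrer, "/", .data$n),
                top1 = paste0(.data$top1, "/", .data$n),
                top2 = paste0(.data$top2, "/", .data$n),
                top3 = paste0(.data$top3, "/", .data$n))
  print(as.data.frame(select(tab, "diagnosis", "referrer", "top1", "top2", "top3")),
        row.names = FALSE)
  tot <- x$overall
  cat("\nTotal: ", paste0(tot$correct, "/", tot$n, collapse = " | "), "\n", sep = "")
  cat("Overall accuracy (%): ",
      paste0(tot$measure, "=", formatC(tot$accuracy, format = "f", digits = 1),
             collapse = ", "), "\n", sep = "")
  urg <- x$urgent
  if (urg$n[1] > 0) {
    cat("Urgent subset (%):    ",
        paste0(urg$measure, "=", formatC(urg$accuracy, format = "f", digits = 1),
               collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$urgency)) {
    cat("\nUrgency triage (top diagnosis):\n")
    m <- x$urgency$metrics
    for (i in seq_len(nrow(m))) {
      cat("  ", m$metric[i], ": ",
          formatC(m$percent[i], format = "f", digits = 1), "% (",
          m$x[i], "/", m$n[i], "; ", round((1 - x$alpha) * 100), "% CI: ",
          m$ci_lower[i], "-", m$ci_upper[i], "%)\n", sep = "")
    }
  }
  invisible(x)
}

#' Export an evaluation report as JSON
#'
#' Machine-readable counterpart of the printed report; round-trips all
#' counts.
#'
#' @param x A `redeye_eval`.
#' @param path Optional file path; when `NULL`, the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
eval_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "redeye_eval"))
  payload <- list(
    concordance = x$concordance,
    overall = x$overall,
    urgent = x$urgent,
    non_urgent = x$non_urgent,
    alpha = x$alpha
  )
  if (!is.null(x$urgency)) payload$urgency <- x$urgency
  if (is.null(path)) {
    jsonlite::toJSON(payload, dataframe = "columns", auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(payload, path, dataframe = "columns",
                         auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
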