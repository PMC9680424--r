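#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an evaluation report
#'
#' One row per (gold cluster, measure): the long form of the concordance
#' table, ready for `dplyr`/`ggplot2`.
#'
#' @param x A `redeye_eval`.
#' @param ... Unused.
#' @return A tibble with columns `diagnosis`, `n`, `measure`, `correct`,
#'   `accuracy`.
#' @export
tidy.redeye_eval <- function(x, ...) {
  x$concordance |>
    tidyr::pivot_longer(cols = c("referrer", "top1", "top2", "top3"),
                        names_to = "measure", values_to = "correct") |>
    mutate(accuracy = ifelse(.data$n > 0, pct1(.data$correct / .data$n), NA_real_))
}

#' One-row summary of an evaluation report
#'
#' Overall and urgent-subset accuracies plus (when computed from raw cases)
#' urgency sensitivity/specificity with their exact CI bounds.
#'
#' @param x A `redeye_eval`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.redeye_eval <- function(x, ...) {
  grab <- function(tab, prefix) {
    setNames(as.list(tab$accuracy), paste0(prefix, tab$measure))
  }
  out <- c(
    list(n = sum(x$concordance$n), n_urgent = x$urgent$n[1]),
    grab(x$overall, "acc_"),
    grab(x$urgent, "urgent_acc_")
  )
  if (!is.null(x$urgency)) {
    m <- x$urgency$metrics
    for (i in seq_len(nrow(m))) {
      out[[m$metric[i]]] <- m$percent[i]
      out[[paste0(m$metric[i], "_ci_lower")]] <- m$ci_lower[i]
      out[[paste0(m$metric[i], "_ci_upper")]] <- m$ci_upper[i]
    }
  }
  as_tibble(out)
}

#' Tidy a diagnostic session
#'
#' Returns the belief trajectory (step 0 is the prior), one row per (step,
#' diagnosis) — the CSV-exportable audit trail.
#'
#' @param x A `redeye_session`.
#' @param ... Unused.
#' @return A tibble with columns `step`, `question`, `answer`, `diagnosis`,
#'   `posterior`.
#' @export
tidy.redeye_session <- function(x, ...) belief_trajectory(x)

#' One-row summary of a diagnostic session
#'
#' @param x A `redeye_session`.
#' @param ... Unused.
#' @return A one-row tibble: questions answered/eliminated, top diagnosis
#'   and posterior, stop state, low-confidence flag.
#' @export
glance.redeye_session <- function(x, ...) {
  diff <- rank_differential(x$belief, x$kb)
  tibble(
    n_answered = nrow(x$answered),
    n_eliminated = length(x$eliminated),
    top_diagnosis = diff$diagnosis[1],
    top_posterior = diff$posterior[1],
    stopped = x$stopped,
    stop_reason = x$stop_reason,
    low_confidence = x$low_confidence
  )
}
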