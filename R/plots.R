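#' Plot a ranked differential diagnosis
#'
#' Horizontal bar chart of the current differential, most likely diagnosis
#' on top, urgent conditions highlighted. The same view the interactive
#' front-end renders as text.
#'
#' @param object A `redeye_belief`.
#' @param kb The matching `redeye_kb`.
#' @param top How many diagnoses to show (urgent ones with positive
#'   posterior are always kept).
#' @param ... Unused.
#' @return A `ggplot` object.
#' @examples
#' kb <- default_kb()
#' autoplot(init_belief(kb), kb, top = 8)
#' @export
autoplot.redeye_belief <- function(object, kb, top = 10, ...) {
  diff <- rank_differential(object, kb, top = top)
  diff$name <- factor(diff$name, levels = rev(diff$name))
  ggplot2::ggplot(diff, ggplot2::aes(x = .data$posterior, y = .data$name,
                                     fill = .data$urgent)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey55", `TRUE` = "firebrick"),
                               labels = c(`FALSE` = "routine", `TRUE` = "urgent"),
                               name = NULL) +
    ggplot2::scale_x_continuous(labels = function(x) paste0(100 * x, "%"),
                                limits = c(0, NA)) +
    ggplot2::labs(x = "posterior probability", y = NULL,
                  title = "Differential diagnosis") +
    ggplot2::theme_minimal()
}

#' Plot evaluation accuracies
#'
#' Grouped bars of referrer vs algorithm top-1/2/3 accuracy, overall and
#' (when present) for the urgent subset.
#'
#' @param object A `redeye_eval`.
#' @param ... Unused.
#' @return A `ggplot` object.
#' @export
autoplot.redeye_eval <- function(object, ...) {
  dat <- bind_rows(
    mutate(object$overall, subset = "all cases"),
    if (object$urgent$n[1] > 0) mutate(object$urgent, subset = "urgent subset")
  )
  dat$measure <- factor(dat$measure, levels = c("referrer", "top1", "top2", "top3"),
                        labels = c("Referrer", "Top 1", "Top 2", "Top 3"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$measure, y = .data$accuracy,
                                    fill = .data$subset)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_brewer(palette = "Paired", name = NULL) +
    ggplot2::labs(x = NULL, y = "accuracy (%)",
                  title = "Diagnostic accuracy") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal()
}

#' Plot a session's belief trajectory
#'
#' Posterior of each diagnosis after every answered question; the visual
#' audit trail of a workup.
#'
#' @param object A `redeye_session`.
#' @param top Show only diagnoses whose posterior ever reaches this rank or
#'   better (default 5) to keep the legend readable.
#' @param ... Unused.
#' @return A `ggplot` object.
#' @export
autoplot.redeye_session <- function(object, top = 5, ...) {
  traj <- belief_trajectory(object)
  keep <- traj |>
    group_by(.data$diagnosis) |>
    summarise(peak = max(.data$posterior), .groups = "drop") |>
    arrange(desc(.data$peak)) |>
    head(top) |>
    pull("diagnosis")
  traj <- filter(traj, .data$diagnosis %in% keep)
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$step, y = .data$posterior,
                                     colour = .data$diagnosis)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "question number (0 = prior)", y = "posterior probability",
                  title = "Belief trajectory") +
    ggplot2::theme_minimal()
}
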