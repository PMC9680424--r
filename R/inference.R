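#' Initialize the belief (differential) from KB priors
#'
#' The belief is the engine's differential diagnosis: a normalized
#' probability vector over the KB's diagnoses, represented as a tibble so it
#' pipes into `dplyr`/`ggplot2` directly.
#'
#' @param kb A `redeye_kb`.
#' @return A `redeye_belief` tibble with columns `diagnosis` and `prob`
#'   (summing to 1).
#' @examples
#' init_belief(default_kb())
#' @export
init_belief <- function(kb) {
  stopifnot(inherits(kb, "redeye_kb"))
  w <- kb$diagnoses$prior
  if (all(is.na(w)) || sum(w, na.rm = TRUE) <= 0) {
    abort("cannot initialize belief: all priors are zero",
          class = "redeye_init_error")
  }
  new_belief(kb$diagnoses$id, w / sum(w))
}

new_belief <- function(diagnosis, prob) {
  structure(tibble(diagnosis = diagnosis, prob = as.numeric(prob)),
            class = c("redeye_belief", "tbl_df", "tbl", "data.frame"))
}

belief_vec <- function(belief) setNames(belief$prob, belief$diagnosis)

#' Bayesian update of the belief for one answered question
#'
#' Applies one step of the sequential Bayes rule under conditional
#' independence of answers given the diagnosis: a YES multiplies each
#' diagnosis's probability by P(YES | diagnosis), a NO by
#' 1 - P(YES | diagnosis), and the result is renormalized. "unknown" carries
#' likelihood 1 for every diagnosis, so the belief is returned unchanged —
#' an undocumented finding is not evidence. A conditional probability of 0
#' (or 1) is a hard rule-out: the corresponding answer sends that
#' diagnosis's posterior to exactly 0.
#'
#' @param belief A `redeye_belief` tibble.
#' @param kb The `redeye_kb` the belief was built from.
#' @param question A question id in `kb`.
#' @param answer `"yes"`, `"no"`, or `"unknown"`.
#' @return The updated, renormalized `redeye_belief`.
#' @section Contradictions: if the answer zeroes out every diagnosis that
#'   still had mass, an error of class `"redeye_contradiction"` is raised
#'   identifying the question; interactive callers may catch it and skip the
#'   update.
#' @examples
#' kb <- default_kb()
#' init_belief(kb) |> update_posterior(kb, "pain", "yes")
#' @export
update_posterior <- function(belief, kb, question, answer) {
  stopifnot(inherits(kb, "redeye_kb"))
  if (!is_answer(answer)) {
    abort(paste0("invalid answer: ", answer), class = "redeye_answer_error")
  }
  if (answer == "unknown") {
    return(belief)
  }
  p_yes <- question_yes_prob(kb, question)[belief$diagnosis]
  lik <- if (answer == "yes") p_yes else 1 - p_yes
  post <- belief$prob * lik
  total <- sum(post)
  if (total <= 0) {
    abort(
      paste0("answer '", answer, "' to question '", question,
             "' rules out all remaining diagnoses"),
      class = "redeye_contradiction", question = question, answer = answer
    )
  }
  new_belief(belief$diagnosis, post / total)
}

#' Rank the differential diagnosis
#'
#' Sorts the belief into a display-ready differential: descending posterior,
#' ties broken by KB declaration order (the sort is stable), a numeric score
#' (posterior as a percentage, one decimal) and a visual score (0-10 bar
#' length). Zero-posterior non-urgent diagnoses may be cut from the display
#' via `top`, but urgent diagnoses with any remaining posterior are always
#' retained regardless of rank, so critical conditions stay in view.
#'
#' @param belief A `redeye_belief`.
#' @param kb The matching `redeye_kb`.
#' @param top Keep the first `top` rows (plus all urgent rows with positive
#'   posterior). Default `Inf` keeps everything.
#' @return A tibble with columns `rank`, `diagnosis`, `name`, `urgent`,
#'   `posterior`, `score`, `bar`.
#' @examples
#' kb <- default_kb()
#' rank_differential(init_belief(kb), kb, top = 3)
#' @export
rank_differential <- function(belief, kb, top = Inf) {
  stopifnot(inherits(kb, "redeye_kb"))
  ord <- match(belief$diagnosis, kb$diagnoses$id)
  out <- tibble(
    diagnosis = belief$diagnosis,
    name      = kb$diagnoses$name[ord],
    urgent    = kb$diagnoses$urgent[ord],
    posterior = belief$prob,
    kb_order  = ord
  )
  out <- arrange(out, desc(.data$posterior), .data$kb_order)
  out <- mutate(out,
    rank  = row_number(),
    score = pct1(.data$posterior),
    bar   = as.integer(round_half_up(10 * .data$posterior))
  )
  out <- filter(out, .data$rank <= top | (.data$urgent & .data$posterior > 0))
  select(out, "rank", "diagnosis", "name", "urgent", "posterior", "score", "bar")
}

#' Supporting and refuting evidence for one diagnosis
#'
#' Classifies each answered (non-unknown) question by whether its answer
#' raised or lowered the diagnosis's posterior relative to the field: an
#' answer supports the diagnosis when its likelihood under that diagnosis
#' exceeds the average likelihood across all diagnoses (so the relative
#' posterior went up), and refutes it when below. Neutral answers are
#' omitted.
#'
#' @param session A `redeye_session`.
#' @param diagnosis A diagnosis id in the session's KB.
#' @param tol Likelihoods within `tol` of the average count as neutral.
#' @return A tibble with columns `question`, `text`, `answer`, `likelihood`,
#'   `average`, `direction` (`"support"` or `"refute"`).
#' @export
evidence_for <- function(session, diagnosis, tol = 1e-9) {
  stopifnot(inherits(session, "redeye_session"))
  kb <- session$kb
  if (!(diagnosis %in% kb$diagnoses$id)) {
    abort(paste0("unknown diagnosis id: ", diagnosis),
          class = "redeye_lookup_error")
  }
  answered <- filter(session$answered, .data$answer != "unknown")
  if (nrow(answered) == 0) {
    return(tibble(question = character(), text = character(),
                  answer = character(), likelihood = numeric(),
                  average = numeric(), direction = character()))
  }
  rows <- pmap(answered, function(question, answer) {
    p_yes <- question_yes_prob(kb, question)
    lik <- if (answer == "yes") p_yes else 1 - p_yes
    tibble(
      question   = question,
      text       = kb_question(kb, question)$text,
      answer     = answer,
      likelihood = unname(lik[diagnosis]),
      average    = mean(lik)
    )
  })
  out <- list_rbind(rows)
  out <- mutate(out, direction = dplyr::case_when(
    .data$likelihood > .data$average + tol ~ "support",
    .data$likelihood < .data$average - tol ~ "refute",
    TRUE ~ NA_character_
  ))
  filter(out, !is.na(.data$direction))
}

#' Should the interview stop?
#'
#' Implements the stopping rule: stop when the top diagnosis heavily
#' outweighs the runner-up (top posterior at least `theta` times the second
#' *and* above the `stop_posterior` floor), or when no eligible questions
#' remain. When stopping with a belief still within total-variation 0.05 of
#' the prior, the session is additionally flagged low-confidence: the
#' questioning achieved no discrimination and the ranking is essentially
#' the prior, so the output should not be trusted as a workup.
#'
#' @param session A `redeye_session`.
#' @return A list with `stop` (logical), `reason` (`"dominance"`,
#'   `"exhausted"`, or `NA` when continuing) and `low_confidence`.
#' @export
check_stop <- function(session) {
  stopifnot(inherits(session, "redeye_session"))
  s <- session$kb$settings
  p <- sort(session$belief$prob, decreasing = TRUE)
  top <- p[1]
  second <- if (length(p) > 1) p[2] else 0
  dominance <- (top >= s$theta * second) && (top >= s$stop_posterior)
  exhausted <- length(eligible_questions(session)) == 0
  stop <- dominance || exhausted
  reason <- if (dominance) "dominance" else if (exhausted) "exhausted" else NA_character_
  low_conf <- stop &&
    tv_dist(belief_vec(session$belief),
            belief_vec(init_belief(session$kb))[session$belief$diagnosis]) <= 0.05
  list(stop = stop, reason = reason, low_confidence = low_conf)
}
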