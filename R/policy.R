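#' Questions currently eligible to be asked
#'
#' The eligible bank is the question list minus questions already answered,
#' minus questions eliminated as redundant, minus questions whose
#' prerequisites are not yet satisfied. A redundancy trigger
#' (question, answer) fires as soon as that pair appears among the answers
#' and eliminates its question permanently; a prerequisite pair must be
#' answered exactly as stated before the dependent question becomes
#' eligible. The computation is a pure function of the answers, hence
#' idempotent.
#'
#' @param session A `redeye_session`.
#' @return Character vector of question ids, in KB declaration order.
#' @export
eligible_questions <- function(session) {
  stopifnot(inherits(session, "redeye_session"))
  kb <- session$kb
  answered_pairs <- session$answered
  eliminated <- eliminated_questions(kb, answered_pairs)
  ok <- map_lgl(seq_len(nrow(kb$questions)), function(i) {
    qid <- kb$questions$id[i]
    if (qid %in% answered_pairs$question || qid %in% eliminated) return(FALSE)
    pre <- kb$questions$prerequisites[[i]]
    all(map_lgl(seq_len(nrow(pre)), function(j) {
      any(answered_pairs$question == pre$question[j] &
            answered_pairs$answer == pre$answer[j])
    }))
  })
  kb$questions$id[ok]
}

# questions whose redundancy triggers have fired given the answers so far
eliminated_questions <- function(kb, answered_pairs) {
  fired <- map_lgl(seq_len(nrow(kb$questions)), function(i) {
    red <- kb$questions$redundancy[[i]]
    nrow(red) > 0 && any(map_lgl(seq_len(nrow(red)), function(j) {
      any(answered_pairs$question == red$question[j] &
            answered_pairs$answer == red$answer[j])
    }))
  })
  kb$questions$id[fired]
}

#' Value-of-information score for a candidate question
#'
#' Scores how much asking a question could move the differential: for each
#' answer a in \{YES, NO\}, `d_a` is the total-variation distance between the
#' current belief and the belief updated by that answer. Mode `"max"`
#' (default) takes the larger of the two — the potential pre-test to
#' post-test change under the best-case answer; mode `"expected"` weights
#' each `d_a` by the predictive probability of the answer,
#' P(a) = sum_j prior_j P(a|j). "unknown" never changes the belief and is
#' excluded. An answer that would zero out every diagnosis contributes
#' `d_a = 0`.
#'
#' @param belief A `redeye_belief`.
#' @param kb The matching `redeye_kb`.
#' @param question A question id.
#' @param mode `"max"` or `"expected"`; defaults to the KB setting.
#' @return A one-row tibble: `question`, `score`, `d_yes`, `d_no`, `p_yes`,
#'   `p_no`.
#' @examples
#' kb <- default_kb()
#' voi_score(init_belief(kb), kb, "stain")
#' @export
voi_score <- function(belief, kb, question, mode = NULL) {
  stopifnot(inherits(kb, "redeye_kb"))
  mode <- mode %||% kb$settings$voi_mode
  mode <- match.arg(mode, c("max", "expected"))
  pre <- belief_vec(belief)
  p_yes_given <- question_yes_prob(kb, question)[belief$diagnosis]
  p_yes <- sum(pre * p_yes_given)
  d <- map_dbl(c(yes = "yes", no = "no"), function(a) {
    post <- tryCatch(
      update_posterior(belief, kb, question, a),
      redeye_contradiction = function(e) NULL
    )
    if (is.null(post)) 0 else tv_dist(pre, belief_vec(post))
  })
  score <- switch(mode,
    max      = max(d),
    expected = p_yes * d[["yes"]] + (1 - p_yes) * d[["no"]]
  )
  tibble(question = question, score = score,
         d_yes = d[["yes"]], d_no = d[["no"]],
         p_yes = p_yes, p_no = 1 - p_yes)
}

#' VOI scores for every eligible question
#'
#' @param session A `redeye_session`.
#' @param mode `"max"` or `"expected"`; defaults to the KB setting.
#' @return A tibble of [voi_score()] rows, one per eligible question, in KB
#'   order (export this per step for an audit trail of the question policy).
#' @export
voi_table <- function(session, mode = NULL) {
  stopifnot(inherits(session, "redeye_session"))
  ids <- eligible_questions(session)
  if (length(ids) == 0) {
    return(tibble(question = character(), score = numeric(),
                  d_yes = numeric(), d_no = numeric(),
                  p_yes = numeric(), p_no = numeric()))
  }
  list_rbind(map(ids, function(q) voi_score(session$belief, session$kb, q, mode)))
}

#' Choose the next question
#'
#' The opening questions are asked first, in KB declaration order; once all
#' (still-eligible) opening questions are answered, the eligible question
#' with the highest value-of-information score is chosen, ties broken by KB
#' declaration order. Deterministic: identical state yields an identical
#' selection.
#'
#' @param session A `redeye_session`.
#' @param mode VOI mode override (see [voi_score()]).
#' @return A question id, or `NA_character_` when no eligible question
#'   remains.
#' @export
select_next_question <- function(session, mode = NULL) {
  stopifnot(inherits(session, "redeye_session"))
  eligible <- eligible_questions(session)
  if (length(eligible) == 0) return(NA_character_)
  opening <- session$kb$questions$id[session$kb$questions$opening]
  open_left <- opening[opening %in% eligible]
  if (length(open_left) > 0) return(open_left[1])
  scores <- voi_table(session, mode)
  # which.max keeps the first maximum; rows are already in KB order
  scores$question[which.max(scores$score)]
}
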