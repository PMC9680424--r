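#' Start a diagnostic session
#'
#' A session holds the KB, the current belief, the ordered answer log, the
#' set of questions eliminated as redundant, the advice already emitted, the
#' stop state, and a step-by-step belief trajectory for audit. Sessions are
#' immutable values: [answer_question()] returns an updated copy.
#'
#' @param kb A `redeye_kb`.
#' @return A `redeye_session`.
#' @examples
#' s <- new_session(default_kb())
#' select_next_question(s)
#' @export
new_session <- function(kb) {
  stopifnot(inherits(kb, "redeye_kb"))
  belief <- init_belief(kb)
  structure(
    list(
      kb = kb,
      belief = belief,
      answered = tibble(question = character(), answer = character()),
      eliminated = character(),
      advice_emitted = character(),
      stopped = FALSE,
      stop_reason = NA_character_,
      low_confidence = FALSE,
      trajectory = trajectory_row(0L, NA_character_, NA_character_, belief)
    ),
    class = "redeye_session"
  )
}

trajectory_row <- function(step, question, answer, belief) {
  tibble(step = step, question = question, answer = answer,
         diagnosis = belief$diagnosis, posterior = belief$prob)
}

#' Record one answer in a session
#'
#' Updates the belief by Bayes' rule, logs the answer, re-evaluates
#' redundancy eliminations and advice rules, and re-checks the stopping
#' rule. Advice rules fire at most once per session, at the first update
#' after which their whole condition holds.
#'
#' @param session A `redeye_session`.
#' @param question An unanswered question id.
#' @param answer `"yes"`, `"no"`, or `"unknown"` (anything [parse_answer()]
#'   accepts).
#' @param on_contradiction `"error"` (default): an answer that zeroes out
#'   every diagnosis raises a `redeye_contradiction` error; `"skip"`: the
#'   update is skipped with a warning and the answer is logged as asked —
#'   the interactive front-end uses this so one inconsistent answer cannot
#'   kill a session.
#' @return The updated `redeye_session`. New advice messages (if any) are in
#'   `attr(, "new_advice")`.
#' @export
answer_question <- function(session, question, answer,
                            on_contradiction = c("error", "skip")) {
  stopifnot(inherits(session, "redeye_session"))
  on_contradiction <- match.arg(on_contradiction)
  answer <- parse_answer(answer)
  if (is.na(answer)) {
    abort("unparseable answer", class = "redeye_answer_error")
  }
  if (question %in% session$answered$question) {
    abort(paste0("question already answered: ", question),
          class = "redeye_reask_error")
  }
  kb_question(session$kb, question)  # errors on unknown id

  belief <- if (on_contradiction == "error") {
    update_posterior(session$belief, session$kb, question, answer)
  } else {
    tryCatch(
      update_posterior(session$belief, session$kb, question, answer),
      redeye_contradiction = function(e) {
        warn(paste0("skipped contradictory update: ", conditionMessage(e)))
        session$belief
      }
    )
  }

  session$belief <- belief
  session$answered <- bind_rows(session$answered,
                                tibble(question = question, answer = answer))
  session$eliminated <- eliminated_questions(session$kb, session$answered)
  session$trajectory <- bind_rows(
    session$trajectory,
    trajectory_row(nrow(session$answered), question, answer, belief)
  )

  new_advice <- fire_advice(session)
  session$advice_emitted <- c(session$advice_emitted, new_advice$id)

  st <- check_stop(session)
  session$stopped <- st$stop
  session$stop_reason <- st$reason
  session$low_confidence <- st$low_confidence

  attr(session, "new_advice") <- new_advice$message
  session
}

# advice rules whose conditions hold now and which have not fired yet
fire_advice <- function(session) {
  adv <- session$kb$advice
  if (nrow(adv) == 0) return(tibble(id = character(), message = character()))
  bv <- belief_vec(session$belief)
  ok <- map_lgl(seq_len(nrow(adv)), function(i) {
    if (adv$id[i] %in% session$advice_emitted) return(FALSE)
    cond <- adv$conditions[[i]]
    holds <- all(map_lgl(seq_len(nrow(cond)), function(j) {
      any(session$answered$question == cond$question[j] &
            session$answered$answer == cond$answer[j])
    }))
    if (!holds) return(FALSE)
    if (!is.na(adv$diagnosis[i]) && !is.na(adv$min_posterior[i])) {
      return(bv[[adv$diagnosis[i]]] >= adv$min_posterior[i])
    }
    TRUE
  })
  adv[ok, c("id", "message")]
}

#' Run an interactive (or scripted) diagnostic interview
#'
#' Loops: pick the next question ([select_next_question()]), read an answer,
#' update the belief, print the re-ranked differential with numeric and
#' visual scores, print any advice the moment its rule fires, and stop when
#' the stopping rule triggers, the bank is exhausted, or the user types
#' `quit`. Unparseable input is re-prompted; after three strikes the answer
#' is recorded as "unknown".
#'
#' Two scripted modes support testing and batch-like use: `answers` supplies
#' an oracle (named vector, question id -> answer; unlisted questions count
#' as "unknown"), or `input` supplies a connection/character vector of lines
#' consumed in order.
#'
#' @param kb A `redeye_kb`.
#' @param answers Optional named character vector of scripted answers.
#' @param input Optional connection or character vector of input lines
#'   (defaults to `stdin()`).
#' @param output Connection for rendering (default `stdout()`); use
#'   `nullfile()` to silence.
#' @param top Number of differential rows to display after each answer.
#' @return The final `redeye_session`, invisibly.
#' @export
run_interview <- function(kb, answers = NULL, input = NULL, output = stdout(),
                          top = 5) {
  stopifnot(inherits(kb, "redeye_kb"))
  if (is.character(input)) {
    input <- textConnection(input)
    on.exit(close(input), add = TRUE)
  }
  lines_left <- TRUE
  read_line <- function() {
    con <- input %||% stdin()
    x <- readLines(con, n = 1)
    if (length(x) == 0) {
      lines_left <<- FALSE
      return(NA_character_)
    }
    x
  }
  out <- function(...) cat(..., "\n", sep = "", file = output)

  session <- new_session(kb)
  repeat {
    if (session$stopped) break
    qid <- select_next_question(session)
    if (is.na(qid)) {
      session$stopped <- TRUE
      session$stop_reason <- "exhausted"
      session$low_confidence <- check_stop(session)$low_confidence
      break
    }
    q <- kb_question(kb, qid)

    if (!is.null(answers)) {
      ans <- if (qid %in% names(answers)) parse_answer(answers[[qid]]) else "unknown"
      if (is.na(ans)) ans <- "unknown"
    } else {
      ans <- NA_character_
      for (strike in 1:3) {
        out(q$text, " [yes/no/unknown, or quit]")
        raw <- read_line()
        if (!lines_left) break
        if (tolower(trimws(raw)) %in% c("q", "quit", "exit")) {
          session$stopped <- TRUE
          session$stop_reason <- "user"
          session$low_confidence <- check_stop(session)$low_confidence
          break
        }
        ans <- parse_answer(raw)
        if (!is.na(ans)) break
        out("Please answer yes, no, or unknown.")
      }
      if (session$stopped) break
      if (!lines_left && is.na(ans)) {
        # input exhausted: treat as a user stop
        session$stopped <- TRUE
        session$stop_reason <- "user"
        session$low_confidence <- check_stop(session)$low_confidence
        break
      }
      if (is.na(ans)) ans <- "unknown"  # three strikes
    }

    session <- answer_question(session, qid, ans, on_contradiction = "skip")
    out(format_differential(rank_differential(session$belief, kb, top = top)))
    for (msg in attr(session, "new_advice")) out(">> ADVICE: ", msg)
  }

  out("Stopped (", session$stop_reason, ")",
      if (session$low_confidence) " -- LOW CONFIDENCE: answers did not discriminate" else "")
  invisible(session)
}

# rank | name | numeric score | 10-cell bar | urgency marker
format_differential <- function(diff) {
  paste(
    sprintf("%2d. %-40s %5.1f [%-10s]%s",
            diff$rank, diff$name, diff$score,
            strrep("#", diff$bar), ifelse(diff$urgent, " (!)", "")),
    collapse = "\n"
  )
}

#' Diagnose a batch of cases
#'
#' Runs every case through the engine non-interactively: each provided
#' answer is fed in KB declaration order (order is irrelevant — the
#' posterior is a normalized product of per-question likelihoods), then the
#' final differential, top-3, advice, stop reason and low-confidence flag
#' are collected. Columns of `cases` other than `case_id`, `referrer_dx`,
#' `gold_dx` must be KB question ids; questions without a column are treated
#' as "unknown". Contradictory answers are skipped with a warning, as in the
#' interactive front-end.
#'
#' @param cases A tibble/data.frame of cases (see [read_cases()] for the CSV
#'   dialect).
#' @param kb A `redeye_kb`.
#' @return A tibble with one row per case: `case_id`, `top1`, `top2`,
#'   `top3`, `differential` (list column of full rankings), `advice` (list
#'   column of messages), `stop_reason`, `low_confidence`.
#' @examples
#' kb <- default_kb()
#' cases <- tibble::tibble(case_id = "c1", stain = "yes", opacity = "yes")
#' batch_diagnose(cases, kb)
#' @export
batch_diagnose <- function(cases, kb) {
  stopifnot(is.data.frame(cases), inherits(kb, "redeye_kb"))
  cases <- as_tibble(cases)
  if (!("case_id" %in% names(cases))) {
    cases$case_id <- sprintf("case_%03d", seq_len(nrow(cases)))
  }
  reserved <- c("case_id", "referrer_dx", "gold_dx")
  qcols <- setdiff(names(cases), reserved)
  unknown_cols <- setdiff(qcols, kb$questions$id)
  if (length(unknown_cols)) {
    abort(paste0("case columns do not map onto KB question ids: ",
                 paste(unknown_cols, collapse = ", ")),
          class = "redeye_column_error")
  }
  # feed answers in KB declaration order
  qcols <- kb$questions$id[kb$questions$id %in% qcols]

  # light inner loop over plain vectors; semantics identical to feeding the
  # answers through answer_question() one by one (a tested invariant)
  yes_mat <- kb_yes_matrix(kb)
  prior <- belief_vec(init_belief(kb))
  adv <- kb$advice
  theta <- kb$settings$theta
  stop_post <- kb$settings$stop_posterior

  rows <- map(seq_len(nrow(cases)), function(i) {
    p <- prior
    ans_q <- character(0)
    ans_a <- character(0)
    fired <- character(0)
    for (qid in qcols) {
      ans <- parse_answer(cases[[qid]][i])
      if (is.na(ans)) ans <- "unknown"
      if (ans != "unknown") {
        lik <- if (ans == "yes") yes_mat[, qid] else 1 - yes_mat[, qid]
        np <- p * lik
        tot <- sum(np)
        if (tot <= 0) {
          warn(paste0("case ", cases$case_id[i], ": skipped contradictory answer '",
                      ans, "' to question '", qid, "'"))
        } else {
          p <- np / tot
        }
      }
      ans_q <- c(ans_q, qid)
      ans_a <- c(ans_a, ans)
      for (j in seq_len(nrow(adv))) {
        if (adv$id[j] %in% fired) next
        cond <- adv$conditions[[j]]
        holds <- all(vapply(seq_len(nrow(cond)), function(r) {
          any(ans_q == cond$question[r] & ans_a == cond$answer[r])
        }, logical(1)))
        if (holds && (is.na(adv$diagnosis[j]) || is.na(adv$min_posterior[j]) ||
                      p[[adv$diagnosis[j]]] >= adv$min_posterior[j])) {
          fired <- c(fired, adv$id[j])
        }
      }
    }
    diff <- rank_differential(new_belief(names(p), unname(p)), kb)
    sp <- sort(p, decreasing = TRUE)
    dominance <- sp[1] >= theta * (if (length(sp) > 1) sp[2] else 0) &&
      sp[1] >= stop_post
    tibble(
      case_id = cases$case_id[i],
      top1 = diff$diagnosis[1],
      top2 = diff$diagnosis[2],
      top3 = diff$diagnosis[3],
      differential = list(diff),
      advice = list(adv$message[match(fired, adv$id)]),
      stop_reason = if (dominance) "dominance" else "exhausted",
      low_confidence = tv_dist(p, prior) <= 0.05
    )
  })
  list_rbind(rows)
}

#' @export
print.redeye_session <- function(x, ...) {
  cat("<redeye_session> ", nrow(x$answered), " answered, ",
      length(x$eliminated), " eliminated, stopped=", x$stopped,
      if (!is.na(x$stop_reason)) paste0(" (", x$stop_reason, ")") else "",
      if (x$low_confidence) ", LOW CONFIDENCE" else "", "\n", sep = "")
  print(head(rank_differential(x$belief, x$kb), 5))
  invisible(x)
}

#' Export a session's belief trajectory
#'
#' One row per (step, diagnosis): the posterior after each answer, step 0
#' being the prior. Write with [readr::write_csv()] for an audit file.
#'
#' @param session A `redeye_session`.
#' @return A tibble with columns `step`, `question`, `answer`, `diagnosis`,
#'   `posterior`.
#' @export
belief_trajectory <- function(session) {
  stopifnot(inherits(session, "redeye_session"))
  session$trajectory
}
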