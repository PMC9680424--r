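#' Parse free-text answers into yes/no/unknown
#'
#' Maps user input onto the three-valued answer scale used by the engine.
#' Parsing is case-insensitive; blank or missing input means "unknown"
#' (an undocumented finding carries no evidence). Unrecognised text yields
#' `NA`, so an interactive caller can re-prompt.
#'
#' @param x Character vector of raw answers.
#' @return Character vector over `"yes"`, `"no"`, `"unknown"`, with `NA` for
#'   unparseable input.
#' @examples
#' parse_answer(c("Yes", "N", "I don't know", "", "maybe"))
#' @export
parse_answer <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[is.na(x)] <- ""
  out <- rep(NA_character_, length(x))
  out[x %in% c("y", "yes")] <- "yes"
  out[x %in% c("n", "no")] <- "no"
  out[x %in% c("", "u", "unknown", "unk", "dk", "idk",
               "i don't know", "i dont know", "don't know", "dont know",
               "?", "na")] <- "unknown"
  out
}

is_answer <- function(x) x %in% ANSWER_LEVELS

# Half-up decimal rounding (clinical-report style). base::round() rounds
# half to even, which prints 84.65 -> 84.6; reports expect 84.7.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# posterior as a percentage, one decimal
pct1 <- function(p) round_half_up(100 * p, 1)

# total variation distance between two probability vectors
tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

`%||%` <- function(a, b) if (is.null(a)) b else a
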