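# Stage vocabulary and alias handling.

#' The five-stage sleep scoring vocabulary
#'
#' Returns the ordered vocabulary of sleep stages used in all agreement
#' statistics: wake (`W`), the three non-REM depth levels (`N1`, `N2`, `N3`)
#' and REM (`R`). The unclassified code `U` (see [stage_unscored()]) is a
#' permitted annotation but never part of this vocabulary.
#'
#' @return Character vector of length five.
#' @export
#' @examples
#' sleep_stages()
sleep_stages <- function() {
  c("W", "N1", "N2", "N3", "R")
}

#' The unclassified stage code
#'
#' Scorers may mark an epoch `U` (unclassified) when the signals are too
#' corrupted to stage it reliably. `U` epochs are removed before any
#' agreement statistic is computed.
#'
#' @return The string `"U"`.
#' @export
stage_unscored <- function() "U"

all_stage_codes <- function() c(sleep_stages(), stage_unscored())

#' Default stage alias table
#'
#' Mapping from common hypnogram export tokens to the canonical stage codes.
#' Matching is case-insensitive; numeric codes follow the widespread
#' 0/1/2/3/5 convention with 9 (or `?`) for unclassified.
#'
#' @return Named character vector: names are accepted tokens (lower case),
#'   values are canonical codes.
#' @export
#' @examples
#' default_stage_aliases()[["rem"]]
default_stage_aliases <- function() {
  c(
    "wake" = "W", "w" = "W", "0" = "W",
    "n1" = "N1", "1" = "N1",
    "n2" = "N2", "2" = "N2",
    "n3" = "N3", "3" = "N3",
    "rem" = "R", "r" = "R", "5" = "R",
    "u" = "U", "?" = "U", "9" = "U"
  )
}

# Map raw tokens to canonical codes; `where` describes the source for error
# messages, `lines` gives the file line of each token when known.
normalize_stage_tokens <- function(tokens, aliases = default_stage_aliases(),
                                   where = "input", lines = NULL) {
  key <- tolower(trimws(as.character(tokens)))
  out <- unname(aliases[key])
  bad <- which(is.na(out))
  if (length(bad) > 0L) {
    i <- bad[1L]
    loc <- if (!is.null(lines)) sprintf(" (line %d)", lines[i]) else ""
    stop(sprintf("unknown stage code '%s' in %s%s", tokens[i], where, loc),
         call. = FALSE)
  }
  out
}

assert_stages <- function(stages, allow_u = TRUE, what = "stages") {
  ok <- if (allow_u) all_stage_codes() else sleep_stages()
  bad <- setdiff(unique(stages), ok)
  if (length(bad) > 0L) {
    stop(sprintf("%s contain inadmissible code(s): %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(stages)
}
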