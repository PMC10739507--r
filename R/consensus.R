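# Majority-vote consensus staging across a rater panel.

#' Majority-vote consensus over a panel of manual scorers
#'
#' Per retained epoch, assigns the stage chosen by a strict plurality of at
#' least two raters. With the usual three-rater panel this is the classic
#' majority vote: full agreement (all three identical), partial agreement
#' (exactly two identical), or non-consensus (all three different). For
#' panels of four or more raters, a tie at the top count is also treated as
#' non-consensus.
#'
#' Epochs without a consensus stage are marked `NA` in `consensus` and are
#' the epochs discarded from machine-vs-majority agreement analyses.
#'
#' @param panel A [align_and_filter()] staging set restricted to the manual
#'   raters; must contain five-stage calls only (`U` filtering is upstream).
#' @return An object of class `consensus_result` with fields `consensus`
#'   (character vector, `NA` where no consensus), `n_full`, `n_partial`,
#'   `n_nonconsensus`, `n_epochs`, and `scorer_ids`.
#' @export
#' @examples
#' a <- hypnogram(c("W", "W", "N1"), "r1", "t1")
#' b <- hypnogram(c("W", "N1", "N2"), "r1", "t2")
#' c <- hypnogram(c("W", "N2", "N3"), "r1", "t3")
#' majority_vote(align_and_filter(list(a, b, c)))
majority_vote <- function(panel) {
  stopifnot(inherits(panel, "staging_set"))
  mat <- panel$stages
  if (any(mat == stage_unscored())) {
    stop("U stages present in consensus panel; run align_and_filter first",
         call. = FALSE)
  }
  k <- ncol(mat)
  stages <- sleep_stages()
  idx <- matrix(match(mat, stages), nrow = nrow(mat))
  cons <- character(nrow(mat))
  top <- integer(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    counts <- tabulate(idx[i, ], nbins = 5L)
    m <- max(counts)
    top[i] <- m
    winners <- which(counts == m)
    cons[i] <- if (m >= 2L && length(winners) == 1L) stages[winners]
               else NA_character_
  }
  structure(
    list(
      consensus = cons,
      n_full = sum(top == k),
      n_partial = sum(!is.na(cons) & top < k),
      n_nonconsensus = sum(is.na(cons)),
      n_epochs = nrow(mat),
      scorer_ids = panel$scorer_ids
    ),
    class = "consensus_result"
  )
}

#' @export
print.consensus_result <- function(x, ...) {
  pct <- function(n) sprintf("%d (%.2f%%)", n, 100 * n / x$n_epochs)
  cat(sprintf("majority vote over %d raters, %d epochs\n",
              length(x$scorer_ids), x$n_epochs))
  cat("  full agreement:   ", pct(x$n_full), "\n")
  cat("  partial agreement:", pct(x$n_partial), "\n")
  cat("  non-consensus:    ", pct(x$n_nonconsensus), "\n")
  invisible(x)
}

#' Export a consensus sequence as a hypnogram
#'
#' Non-consensus epochs are written with the `U` code, the convention used
#' when plotting a majority-vote hypnogram next to the raters' own staging.
#'
#' @param x A `consensus_result`.
#' @param recording_id Recording identifier for the output hypnogram.
#' @return A [hypnogram()] with scorer id `"majority"`.
#' @export
consensus_hypnogram <- function(x, recording_id) {
  stopifnot(inherits(x, "consensus_result"))
  stages <- x$consensus
  stages[is.na(stages)] <- stage_unscored()
  hypnogram(stages, recording_id, "majority")
}
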