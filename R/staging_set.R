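# Multi-scorer alignment and epoch retention filtering.

#' Align multiple scorers' hypnograms and apply epoch retention rules
#'
#' Builds the epoch-aligned stage matrix for one recording from two or more
#' scorers. Because scorers may stop staging a few epochs before the end of
#' the recording, all sequences are first truncated to the shortest staged
#' length (truncation is at the end only; all scorers share the lights-off
#' origin). Then, when `drop_u` is `TRUE` (the default and the rule used in
#' every analysis), any epoch in which at least one scorer assigned the
#' unclassified stage `U` is removed, so that every retained epoch carries a
#' proper five-stage call from every scorer.
#'
#' @param hypnograms List of at least two [hypnogram()] objects for the same
#'   recording.
#' @param drop_u Remove epochs containing `U` in any column (default `TRUE`).
#' @return An object of class `staging_set` with fields:
#'   \describe{
#'     \item{recording_id}{the shared recording identifier}
#'     \item{scorer_ids}{column order, following the input order}
#'     \item{stages}{character matrix, retained epochs x scorers}
#'     \item{retained_epochs}{0-based original epoch indices of the rows}
#'     \item{n_truncated}{epochs dropped by end-of-recording truncation,
#'       counted against the longest input}
#'     \item{n_u_dropped}{epoch rows removed because some scorer marked `U`}
#'   }
#' @export
#' @examples
#' a <- hypnogram(c("W", "N1", "N2", "N2"), "r1", "A")
#' b <- hypnogram(c("W", "N1", "N2"), "r1", "B")
#' align_and_filter(list(a, b))$retained_epochs
align_and_filter <- function(hypnograms, drop_u = TRUE) {
  if (!is.list(hypnograms) || length(hypnograms) < 2L) {
    stop("alignment requires at least 2 hypnograms", call. = FALSE)
  }
  stopifnot(all(vapply(hypnograms, inherits, logical(1), "hypnogram")))
  rec_ids <- unique(vapply(hypnograms, `[[`, character(1), "recording_id"))
  if (length(rec_ids) != 1L) {
    stop(sprintf("hypnograms belong to different recordings: %s",
                 paste(rec_ids, collapse = ", ")), call. = FALSE)
  }
  lens <- vapply(hypnograms, length, integer(1))
  n_min <- min(lens)
  n_max <- max(lens)
  mat <- vapply(hypnograms, function(h) h$stages[seq_len(n_min)],
                character(n_min))
  if (n_min == 1L) mat <- matrix(mat, nrow = 1L)
  keep <- if (drop_u) {
    rowSums(mat == stage_unscored()) == 0L
  } else {
    rep(TRUE, n_min)
  }
  if (!any(keep)) {
    stop(structure(
      class = c("hypnoagree_empty_set", "error", "condition"),
      list(message = sprintf(
             "recording %s: no epochs retained after filtering", rec_ids),
           call = NULL)))
  }
  structure(
    list(
      recording_id = rec_ids,
      scorer_ids = vapply(hypnograms, `[[`, character(1), "scorer_id"),
      stages = mat[keep, , drop = FALSE],
      retained_epochs = which(keep) - 1L,
      n_truncated = n_max - n_min,
      n_u_dropped = sum(!keep)
    ),
    class = "staging_set"
  )
}

#' @export
print.staging_set <- function(x, ...) {
  cat(sprintf(
    "staging_set: recording %s, %d scorers (%s), %d retained epochs\n",
    x$recording_id, length(x$scorer_ids),
    paste(x$scorer_ids, collapse = ", "), nrow(x$stages)))
  cat(sprintf("  dropped: %d by end truncation, %d containing U\n",
              x$n_truncated, x$n_u_dropped))
  invisible(x)
}

# Column extraction by scorer id.
set_column <- function(set, scorer_id) {
  j <- match(scorer_id, set$scorer_ids)
  if (is.na(j)) {
    stop(sprintf("scorer '%s' not in staging set", scorer_id), call. = FALSE)
  }
  set$stages[, j]
}
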