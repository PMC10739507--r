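# Hypnogram container and plain-text I/O.
#
# One hypnogram = one scorer's per-epoch stage sequence for one recording,
# at the fixed 30-second epoch grid between lights-off and lights-on.

EPOCH_SECONDS <- 30

#' Construct a hypnogram
#'
#' A hypnogram is one scorer's ordered per-epoch stage sequence for one
#' recording. Epochs are fixed at 30 seconds; the sequence covers the staged
#' part of the lights-off to lights-on window.
#'
#' @param stages Character vector of stage codes (`W`, `N1`, `N2`, `N3`, `R`,
#'   `U`), one per 30-s epoch, ordered from lights-off. Must be non-empty.
#' @param recording_id,scorer_id Identifiers for the recording and scorer.
#' @param lights_off,lights_on Clock times (`"HH:MM:SS"` strings) bounding
#'   the in-bed window; optional metadata, `NA` if unknown.
#' @return An object of class `hypnogram`.
#' @export
#' @examples
#' h <- hypnogram(c("W", "W", "N1", "N2"), "rec01", "tech1")
#' length(h$stages)
hypnogram <- function(stages, recording_id, scorer_id,
                      lights_off = NA_character_, lights_on = NA_character_) {
  stages <- as.character(stages)
  if (length(stages) == 0L) {
    stop("a hypnogram must contain at least one epoch", call. = FALSE)
  }
  assert_stages(stages, allow_u = TRUE, what = "hypnogram stages")
  structure(
    list(
      recording_id = as.character(recording_id),
      scorer_id = as.character(scorer_id),
      stages = stages,
      lights_off = lights_off,
      lights_on = lights_on,
      epoch_seconds = EPOCH_SECONDS
    ),
    class = "hypnogram"
  )
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("hypnogram: recording %s, scorer %s, %d epochs (%.1f min)\n",
              x$recording_id, x$scorer_id, length(x$stages),
              length(x$stages) * x$epoch_seconds / 60))
  tab <- table(factor(x$stages, levels = all_stage_codes()))
  print(tab[tab > 0])
  invisible(x)
}

#' @export
length.hypnogram <- function(x) length(x$stages)

#' Read a hypnogram from a per-scorer CSV file
#'
#' The expected dialect is a two-column CSV with header
#' `epoch_index,stage`: 0-based epoch indices, dense from 0, one row per
#' 30-s epoch, stage tokens resolved through an alias table.
#'
#' @param path Path to the CSV file.
#' @param recording_id,scorer_id Identity metadata (typically from the study
#'   manifest; the file itself carries only the sequence).
#' @param lights_off,lights_on Optional clock-time metadata.
#' @param aliases Stage alias table, see [default_stage_aliases()].
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path, recording_id = NA_character_,
                           scorer_id = NA_character_,
                           lights_off = NA_character_,
                           lights_on = NA_character_,
                           aliases = default_stage_aliases()) {
  if (!file.exists(path)) {
    stop(sprintf("hypnogram file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("integer", "character"))
  if (!all(c("epoch_index", "stage") %in% names(df))) {
    stop(sprintf("%s: expected columns 'epoch_index,stage'", path),
         call. = FALSE)
  }
  if (nrow(df) == 0L) {
    stop(sprintf("%s: empty hypnogram file", path), call. = FALSE)
  }
  ord <- order(df$epoch_index)
  df <- df[ord, , drop = FALSE]
  n <- nrow(df)
  if (!identical(df$epoch_index, 0:(n - 1L))) {
    expected <- 0:(n - 1L)
    miss <- setdiff(expected, df$epoch_index)
    if (length(miss) > 0L) {
      stop(sprintf("%s: gap in epoch indices (missing index %d)",
                   path, miss[1L]), call. = FALSE)
    }
    stop(sprintf("%s: epoch indices must be dense and 0-based", path),
         call. = FALSE)
  }
  # file line of each (sorted) row: original position + 1 header line
  stages <- normalize_stage_tokens(df$stage, aliases,
                                   where = path, lines = ord + 1L)
  hypnogram(stages, recording_id, scorer_id, lights_off, lights_on)
}

#' Write a hypnogram to the per-scorer CSV dialect
#'
#' Inverse of [read_hypnogram()]: writes `epoch_index,stage` rows with
#' 0-based dense indices and canonical stage codes, so a read/write round
#' trip reproduces the stage sequence exactly.
#'
#' @param h A [hypnogram()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(h, path) {
  stopifnot(inherits(h, "hypnogram"))
  df <- data.frame(epoch_index = seq_along(h$stages) - 1L,
                   stage = h$stages)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
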