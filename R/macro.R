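# Sleep macrostructure indices from a single hypnogram.

#' Sleep macrostructure indices
#'
#' Derives the standard clinical summary indices from one scorer's
#' hypnogram over its lights-off to lights-on window, with 30-s epoch
#' arithmetic (each epoch contributes 0.5 min). Conventions:
#' \itemize{
#'   \item sleep onset = first epoch staged as any of N1/N2/N3/R;
#'   \item SL (sleep latency) = minutes from lights-off to onset; unscored
#'     `U` epochs before onset count toward the latency;
#'   \item TST (total sleep time) = minutes in N1/N2/N3/R;
#'   \item WASO (wake after sleep onset) = minutes in W or `U` after onset,
#'     terminal wake included, so that SL + TST + WASO = TIB exactly
#'     whenever onset exists;
#'   \item REML (REM latency) = minutes from onset to the first R epoch;
#'   \item SE (sleep efficiency) = 100 x TST / TIB.
#' }
#' SL, REML and WASO are `NA` (missing, not zero) when the recording has no
#' sleep epoch or no REM epoch; downstream reliability analyses drop such
#' recordings pairwise rather than fabricating agreement from zeros.
#'
#' @param h A [hypnogram()].
#' @return Object of class `macro_indices`: a named list with `tib`, `tst`,
#'   `sl`, `reml`, `se`, `waso`, per-stage minutes `t_w`, `t_n1`, `t_n2`,
#'   `t_n3`, `t_r`, and `u_time`, all in minutes except `se` (percent).
#' @export
#' @examples
#' compute_macro(hypnogram(c("W", "W", "N1", "N2", "R"), "r1", "t1"))
compute_macro <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  stages <- h$stages
  n <- length(stages)
  epoch_min <- h$epoch_seconds / 60
  sleep <- stages %in% c("N1", "N2", "N3", "R")
  tib <- n * epoch_min
  tst <- sum(sleep) * epoch_min
  onset <- which(sleep)[1L]                       # NA when no sleep epoch
  first_rem <- which(stages == "R")[1L]
  sl <- if (is.na(onset)) NA_real_ else (onset - 1L) * epoch_min
  reml <- if (is.na(first_rem)) NA_real_ else (first_rem - onset) * epoch_min
  waso <- if (is.na(onset)) NA_real_ else sum(!sleep[onset:n]) * epoch_min
  count_min <- function(code) sum(stages == code) * epoch_min
  structure(
    list(
      tib = tib, tst = tst, sl = sl, reml = reml,
      se = 100 * tst / tib, waso = waso,
      t_w = count_min("W"), t_n1 = count_min("N1"), t_n2 = count_min("N2"),
      t_n3 = count_min("N3"), t_r = count_min("R"),
      u_time = count_min("U")
    ),
    class = "macro_indices"
  )
}

#' @export
print.macro_indices <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "missing", sprintf("%.1f", v))
  cat(sprintf("TIB %.1f min, TST %.1f min, SE %.2f%%\n", x$tib, x$tst, x$se))
  cat(sprintf("SL %s, REML %s, WASO %s (min)\n",
              fmt(x$sl), fmt(x$reml), fmt(x$waso)))
  invisible(x)
}

#' Names of the macrostructure indices used in reliability analyses
#'
#' @return Character vector of the ten index columns of [macro_table()].
#' @export
macro_index_names <- function() {
  c("tst", "sl", "reml", "se", "waso", "t_w", "t_n1", "t_n2", "t_n3", "t_r")
}

#' Per-recording, per-scorer macrostructure table
#'
#' @param hypnograms List of [hypnogram()] objects (any mix of recordings
#'   and scorers).
#' @return Data frame with columns `recording_id`, `scorer_id`, and all
#'   indices from [compute_macro()].
#' @export
macro_table <- function(hypnograms) {
  rows <- lapply(hypnograms, function(h) {
    cbind(data.frame(recording_id = h$recording_id,
                     scorer_id = h$scorer_id),
          as.data.frame(unclass(compute_macro(h))))
  })
  do.call(rbind, rows)
}
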