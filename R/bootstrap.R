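# Recording-level (cluster) bootstrap.
#
# Epochs within a recording are strongly dependent, so resampling is done
# over whole recordings: each resample draws n recordings with replacement
# and re-evaluates the statistic on the pooled resample.

#' Bootstrap configuration
#'
#' @param n_resamples Number of bootstrap resamples (default 10,000).
#' @param ci_lower_pct,ci_upper_pct Percentiles bounding the confidence
#'   interval (default 2.5 and 97.5, a 95\% percentile interval).
#' @param seed Optional integer seed; with a fixed seed results are exactly
#'   reproducible.
#' @return A `bootstrap_config` list.
#' @export
bootstrap_config <- function(n_resamples = 10000L, ci_lower_pct = 2.5,
                             ci_upper_pct = 97.5, seed = NULL) {
  stopifnot(n_resamples >= 1L,
            ci_lower_pct > 0, ci_upper_pct < 100,
            ci_lower_pct < ci_upper_pct)
  structure(list(n_resamples = as.integer(n_resamples),
                 ci_lower_pct = ci_lower_pct,
                 ci_upper_pct = ci_upper_pct,
                 seed = seed),
            class = "bootstrap_config")
}

#' Cluster bootstrap over recordings
#'
#' Draws `n_resamples` samples of the recording list, each of the original
#' size and with replacement, evaluates `statistic` on every resampled
#' list, and summarises the resample distribution: the median is the point
#' estimate and the 2.5th/97.5th percentiles (linear-interpolation
#' percentiles) bound the 95\% interval. `statistic` may return a scalar or
#' a named numeric vector (all components are summarised from the same
#' resamples); components that come back `NA` (undefined, e.g. a stage
#' absent from every resampled recording) are dropped from that component's
#' distribution and counted in `n_defined`.
#'
#' @param recordings List of per-recording data (any type the statistic
#'   accepts, e.g. per-recording confusion matrices).
#' @param statistic Function taking a (resampled, possibly repeating) list
#'   of recordings and returning a numeric scalar or named vector.
#' @param config A [bootstrap_config()].
#' @return Object of class `bootstrap_result`: list with `point` (median
#'   per component), `lower`, `upper`, `plugin` (statistic on the original
#'   list), `n_defined`, `n_resamples`, `n_recordings`.
#' @export
#' @examples
#' recs <- list(c(agree = 80, n = 100), c(agree = 90, n = 100))
#' pooled_opa <- function(rs) {
#'   m <- do.call(rbind, rs); sum(m[, "agree"]) / sum(m[, "n"])
#' }
#' cluster_bootstrap(recs, pooled_opa, bootstrap_config(200, seed = 1))
cluster_bootstrap <- function(recordings, statistic,
                              config = bootstrap_config()) {
  stopifnot(is.list(recordings), length(recordings) >= 1L)
  n <- length(recordings)
  plugin <- statistic(recordings)
  p <- length(plugin)
  nm <- names(plugin)
  if (!is.null(config$seed)) set.seed(config$seed)
  draws <- matrix(NA_real_, nrow = config$n_resamples, ncol = p)
  for (b in seq_len(config$n_resamples)) {
    idx <- sample.int(n, n, replace = TRUE)
    draws[b, ] <- as.numeric(statistic(recordings[idx]))
  }
  n_defined <- as.integer(colSums(!is.na(draws)))
  if (all(n_defined == 0L)) {
    stop("statistic undefined in every bootstrap resample", call. = FALSE)
  }
  summarise <- function(col) {
    v <- draws[, col]
    v <- v[!is.na(v)]
    if (length(v) == 0L) {
      return(c(NA_real_, NA_real_, NA_real_))
    }
    c(stats::median(v),
      stats::quantile(v, config$ci_lower_pct / 100, names = FALSE, type = 7),
      stats::quantile(v, config$ci_upper_pct / 100, names = FALSE, type = 7))
  }
  s <- vapply(seq_len(p), summarise, numeric(3))
  point <- s[1, ]; lower <- s[2, ]; upper <- s[3, ]
  names(point) <- names(lower) <- names(upper) <- nm
  names(n_defined) <- nm
  structure(
    list(point = point, lower = lower, upper = upper,
         plugin = plugin, n_defined = n_defined,
         n_resamples = config$n_resamples, n_recordings = n),
    class = "bootstrap_result"
  )
}

#' Paired bootstrap for a difference of two statistics
#'
#' Evaluates `statistic_a - statistic_b` on every resample, with a single
#' resample driving both statistics (paired resampling: the same resampled
#' recordings feed both sides). This pairing is what makes the CI-sign
#' significance rule meaningful; resampling the two sides independently
#' would inflate the variance of the difference.
#'
#' Significance of each component is read off the percentile CI:
#' `"positive"` if the lower bound exceeds 0, `"negative"` if the upper
#' bound is below 0, otherwise `"none"`.
#'
#' @param recordings List of per-recording data.
#' @param statistic_a,statistic_b Functions as in [cluster_bootstrap()],
#'   returning conformable (equal-length, same names) results.
#' @param config A [bootstrap_config()].
#' @return A `bootstrap_result` with an extra `significant` component
#'   (character vector of `"positive"`/`"negative"`/`"none"`).
#' @export
bootstrap_difference <- function(recordings, statistic_a, statistic_b,
                                 config = bootstrap_config()) {
  diff_stat <- function(rs) statistic_a(rs) - statistic_b(rs)
  out <- cluster_bootstrap(recordings, diff_stat, config)
  out$significant <- ci_significance(out$lower, out$upper)
  out
}

# CI-sign significance rule for difference statistics.
ci_significance <- function(lower, upper) {
  sig <- rep("none", length(lower))
  sig[!is.na(lower) & lower > 0] <- "positive"
  sig[!is.na(upper) & upper < 0] <- "negative"
  sig[is.na(lower) | is.na(upper)] <- NA_character_
  names(sig) <- names(lower)
  sig
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "cluster bootstrap: %d resamples over %d recordings\n",
    x$n_resamples, x$n_recordings))
  df <- data.frame(point = x$point, lower = x$lower, upper = x$upper,
                   n_defined = x$n_defined)
  if (!is.null(x$significant)) df$significant <- x$significant
  print(df, digits = 4)
  invisible(x)
}
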