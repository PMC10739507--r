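# ICC(A,1): absolute-agreement intraclass correlation, single measures,
# two-way layout (subjects x raters, no replication).

#' ICC(A,1): absolute-agreement intraclass correlation
#'
#' Single-measure intraclass correlation under the absolute-agreement
#' definition for a two-way layout with fixed raters and no replication.
#' With n subjects (rows) and k raters (columns), the two-way ANOVA mean
#' squares without replication are
#' \deqn{MSR = k \sum_i (\bar y_{i.} - \bar y)^2 / (n-1)}
#' \deqn{MSC = n \sum_j (\bar y_{.j} - \bar y)^2 / (k-1)}
#' \deqn{MSE = (SST - SSR - SSC) / ((n-1)(k-1))}
#' and
#' \deqn{ICC(A,1) = \frac{MSR - MSE}{MSR + (k-1) MSE + \frac{k}{n}(MSC - MSE)}.}
#'
#' Rows containing any missing value are dropped (and counted); the ICC is
#' `NA` when the denominator is zero (e.g. all ratings identical constants).
#'
#' @param ratings Numeric matrix or data frame, rows = subjects
#'   (recordings), columns = raters (scorers); at least two columns.
#' @return Object of class `icc_result`: list with `icc`, `msr`, `msc`,
#'   `mse`, `n`, `k`, `dropped`, and `interpretation` (see
#'   [interpret_icc()]).
#' @export
#' @examples
#' icc_a1(cbind(a = c(1, 2, 3), b = c(2, 3, 4)))$icc  # 2/3
icc_a1 <- function(ratings) {
  x <- as.matrix(ratings)
  storage.mode(x) <- "double"
  k <- ncol(x)
  if (k < 2L) stop("ICC requires at least 2 raters", call. = FALSE)
  complete <- rowSums(is.na(x)) == 0L
  dropped <- sum(!complete)
  x <- x[complete, , drop = FALSE]
  n <- nrow(x)
  if (n < 2L) {
    stop(structure(
      class = c("hypnoagree_insufficient_data", "error", "condition"),
      list(message = sprintf(
             "ICC needs >= 2 complete subject rows, got %d", n),
           call = NULL)))
  }
  ms <- icc_mean_squares(x)
  msr <- ms$msr; msc <- ms$msc; mse <- ms$mse
  icc <- icc_from_ms(msr, msc, mse, n, k)
  structure(
    list(icc = icc, msr = msr, msc = msc, mse = mse,
         n = n, k = k, dropped = dropped,
         interpretation = interpret_icc(icc)),
    class = "icc_result"
  )
}

# Two-way mean squares without replication for a complete matrix.
icc_mean_squares <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  ssr <- k * sum((rowMeans(x) - grand)^2)
  ssc <- n * sum((colMeans(x) - grand)^2)
  sse <- sum((x - grand)^2) - ssr - ssc
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)))
}

icc_from_ms <- function(msr, msc, mse, n, k) {
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  scale <- max(abs(c(msr, msc, mse, 1e-300)))
  if (abs(denom) < 1e-12 * scale || denom == 0) NA_real_
  else (msr - mse) / denom
}

# Scalar fast path used inside bootstrap loops: NA-row dropping, NA when
# degenerate or fewer than 2 complete rows (never an error).
icc_a1_value <- function(x) {
  x <- x[rowSums(is.na(x)) == 0L, , drop = FALSE]
  n <- nrow(x); k <- ncol(x)
  if (n < 2L) return(NA_real_)
  ms <- icc_mean_squares(x)
  icc_from_ms(ms$msr, ms$msc, ms$mse, n, k)
}

#' @export
print.icc_result <- function(x, ...) {
  if (is.na(x$icc)) {
    cat("ICC(A,1): undefined (degenerate mean squares)\n")
  } else {
    cat(sprintf("ICC(A,1) = %.4f (%s), n = %d subjects, k = %d raters",
                x$icc, x$interpretation, x$n, x$k))
    if (x$dropped > 0) cat(sprintf(", %d rows dropped", x$dropped))
    cat("\n")
  }
  invisible(x)
}

#' Qualitative interpretation bands for ICC values
#'
#' Standard reliability bands: poor below 0.5, moderate in `[0.5, 0.75)`,
#' good in `[0.75, 0.9)`, excellent in `[0.9, 1]`. The 0.9 boundary is
#' assigned to "excellent"; boundaries are applied as half-open intervals.
#'
#' @param value Numeric vector of ICC values (each <= 1), `NA` allowed.
#' @return Character vector of categories, `NA` where the input is `NA`.
#' @export
#' @examples
#' interpret_icc(c(0.3, 0.6755, 0.75, 0.9684))
interpret_icc <- function(value) {
  stopifnot(all(is.na(value) | value <= 1 + 1e-12))
  out <- rep(NA_character_, length(value))
  out[!is.na(value) & value < 0.5] <- "poor"
  out[!is.na(value) & value >= 0.5 & value < 0.75] <- "moderate"
  out[!is.na(value) & value >= 0.75 & value < 0.9] <- "good"
  out[!is.na(value) & value >= 0.9] <- "excellent"
  out
}

#' Average pairwise ICC(A,1) between two scorer groups
#'
#' Averages the pairwise (k = 2) ICC(A,1) over scorer pairs. With identical
#' groups this is the within-panel average over all unordered pairs (three
#' pairs for three technicians; the ICC is symmetric so ordered pairs would
#' give the same value). With distinct groups (e.g. machine vs manual
#' panel) every cross pair contributes. Pairs with an undefined ICC are
#' skipped and counted.
#'
#' @param table Numeric matrix or data frame, rows = recordings, columns
#'   named by scorer id, of one macrostructure index. `NA` entries drop the
#'   recording for pairs involving that scorer.
#' @param group_a,group_b Character vectors of scorer ids (columns of
#'   `table`).
#' @return List with `mean` (average ICC, `NA` if all pairs undefined),
#'   `per_pair` (data frame: `scorer_a`, `scorer_b`, `icc`, `n`, `dropped`),
#'   and `n_undefined`.
#' @export
average_pairwise_icc <- function(table, group_a, group_b) {
  x <- as.matrix(table)
  stopifnot(length(group_a) >= 1L, length(group_b) >= 1L)
  missing_cols <- setdiff(unique(c(group_a, group_b)), colnames(x))
  if (length(missing_cols) > 0L) {
    stop(sprintf("scorers not in table: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (setequal(group_a, group_b)) {
    cmb <- utils::combn(sort(unique(group_a)), 2L)
    pairs <- data.frame(a = cmb[1L, ], b = cmb[2L, ],
                        stringsAsFactors = FALSE)
  } else {
    pairs <- expand.grid(a = group_a, b = group_b,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$a != pairs$b, ]
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    r <- tryCatch(
      icc_a1(x[, c(pairs$a[i], pairs$b[i])]),
      hypnoagree_insufficient_data = function(e) {
        list(icc = NA_real_, n = 0L, dropped = nrow(x))
      })
    data.frame(scorer_a = pairs$a[i], scorer_b = pairs$b[i],
               icc = r$icc, n = r$n, dropped = r$dropped)
  })
  per_pair <- do.call(rbind, res)
  defined <- !is.na(per_pair$icc)
  list(
    mean = if (any(defined)) mean(per_pair$icc[defined]) else NA_real_,
    per_pair = per_pair,
    n_undefined = sum(!defined)
  )
}
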