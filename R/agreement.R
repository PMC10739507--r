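# Confusion matrices and epoch-level agreement statistics.
#
# All statistics are computed on epochs pooled across recordings
# (micro-average): the pooled confusion matrix is the elementwise sum of the
# per-recording matrices, so per-recording matrices are the unit that the
# cluster bootstrap resamples.

#' Cross-tabulate two scorers' stage sequences
#'
#' Builds the 5x5 confusion matrix of epoch counts with the reference scorer
#' on rows and the test scorer on columns, over the five-stage vocabulary.
#'
#' @param reference,test Equal-length character vectors of five-stage calls
#'   for the same epochs (`U` must have been filtered upstream).
#' @param labels Stage vocabulary, default [sleep_stages()].
#' @return A `confusion_matrix`: an integer matrix with dimnames
#'   `reference` x `test`.
#' @export
#' @examples
#' build_confusion(c("W", "W", "N1"), c("W", "N1", "N1"))
build_confusion <- function(reference, test, labels = sleep_stages()) {
  if (length(reference) != length(test)) {
    stop("reference and test sequences differ in length", call. = FALSE)
  }
  if (length(reference) == 0L) {
    stop("cannot build a confusion matrix from zero epochs", call. = FALSE)
  }
  assert_stages(reference, allow_u = FALSE, what = "reference stages")
  assert_stages(test, allow_u = FALSE, what = "test stages")
  m <- table(factor(reference, levels = labels),
             factor(test, levels = labels))
  m <- matrix(as.integer(m), nrow = length(labels),
              dimnames = list(reference = labels, test = labels))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Sum confusion matrices across recordings
#'
#' @param matrices List of `confusion_matrix` objects over the same labels.
#' @return The pooled `confusion_matrix`.
#' @export
pool_confusion <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  out <- Reduce(`+`, matrices)
  structure(out, class = c("confusion_matrix", "matrix"))
}

#' Overall percent agreement
#'
#' Fraction of epochs assigned the same stage by both scorers:
#' trace / grand total.
#'
#' @param m A `confusion_matrix`.
#' @return Proportion in `[0, 1]`.
#' @export
overall_percent_agreement <- function(m) {
  n <- sum(m)
  stopifnot(n >= 1)
  sum(diag(m)) / n
}

#' Cohen's kappa
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with
#' \eqn{p_o} the observed agreement (trace / N) and \eqn{p_e} the expected
#' agreement from the row and column marginals. When both scorers are
#' constant and identical, \eqn{p_e = 1} and kappa is undefined; `NA` is
#' returned rather than a silent 0.
#'
#' @param m A `confusion_matrix`.
#' @return Kappa in `[-1, 1]`, or `NA` when undefined.
#' @export
cohens_kappa <- function(m) {
  n <- sum(m)
  stopifnot(n >= 1)
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (1 - pe < 1e-14) {
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Per-stage agreement statistics
#'
#' For a stage s with TP the diagonal count, `ref_s` the reference row total
#' and `test_s` the test column total out of N pooled epochs:
#' \itemize{
#'   \item PPA (positive percent agreement, sensitivity) = TP / ref_s
#'   \item NPA (negative percent agreement, specificity)
#'     = (N - ref_s - test_s + TP) / (N - ref_s)
#'   \item PPV (positive predictive value) = TP / test_s
#' }
#' A statistic with a zero denominator is `NA` (undefined), never 0.
#'
#' @param m A `confusion_matrix`.
#' @param stage One stage code from the matrix vocabulary.
#' @return Named list with elements `ppa`, `npa`, `ppv`.
#' @export
per_stage_stats <- function(m, stage) {
  labels <- rownames(m)
  if (!stage %in% labels) {
    stop(sprintf("stage '%s' not in matrix vocabulary", stage), call. = FALSE)
  }
  n <- sum(m)
  tp <- m[stage, stage]
  ref_s <- sum(m[stage, ])
  test_s <- sum(m[, stage])
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  list(
    ppa = ratio(tp, ref_s),
    npa = ratio(n - ref_s - test_s + tp, n - ref_s),
    ppv = ratio(tp, test_s)
  )
}

#' All agreement statistics for one confusion matrix
#'
#' @param m A `confusion_matrix`.
#' @return List with `opa`, `kappa`, and `per_stage` (data frame with one
#'   row per stage and columns `stage`, `ppa`, `npa`, `ppv`).
#' @export
agreement_stats <- function(m) {
  labels <- rownames(m)
  per <- do.call(rbind, lapply(labels, function(s) {
    as.data.frame(per_stage_stats(m, s))
  }))
  list(
    opa = overall_percent_agreement(m),
    kappa = cohens_kappa(m),
    per_stage = cbind(data.frame(stage = labels), per)
  )
}

# Flat named vector of all 17 statistics, the unit the bootstrap works on.
# Pure marginal arithmetic (no intermediate tables): this sits inside the
# bootstrap loop.
agreement_vector <- function(m) {
  n <- sum(m)
  d <- diag(m)
  rt <- rowSums(m)
  ct <- colSums(m)
  po <- sum(d) / n
  pe <- sum(rt * ct) / n^2
  kap <- if (1 - pe < 1e-14) NA_real_ else (po - pe) / (1 - pe)
  safe <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  lab <- rownames(m)
  c(opa = po, kappa = kap,
    stats::setNames(safe(d, rt), paste0("ppa_", lab)),
    stats::setNames(safe(n - rt - ct + d, n - rt), paste0("npa_", lab)),
    stats::setNames(safe(d, ct), paste0("ppv_", lab)))
}

#' Directional pairwise agreement averages over a rater panel
#'
#' Two families of averages underpin the machine-vs-panel comparison:
#' \describe{
#'   \item{within-panel}{every ordered pair (reference, test) of manual
#'     raters is evaluated and each statistic averaged over all ordered
#'     pairs (six values for three raters). Ordering matters for PPA/NPA/PPV
#'     because the agreement of rater A referenced on B differs from B
#'     referenced on A; averaging both orders makes the within-panel average
#'     PPA equal to the average PPV for every stage.}
#'   \item{machine-vs-panel}{the machine is always the test scorer and each
#'     manual rater in turn the reference (three values for three raters);
#'     the reverse direction is deliberately not averaged in.}
#' }
#' Statistics undefined for some pairs (zero denominators) are skipped in
#' the average, and the number skipped is reported.
#'
#' @param panel A [align_and_filter()] staging set containing the manual
#'   raters and, if `machine` is given, the machine column.
#' @param machine Scorer id of the automatic scorer in `panel`, or `NULL`
#'   for within-panel averages only.
#' @return List with components `within` and (if requested) `machine`, each
#'   a list of `mean` (named vector of averaged statistics), `n_undefined`
#'   (pairs skipped per statistic), and `n_pairs`.
#' @export
directional_panel_averages <- function(panel, machine = NULL) {
  stopifnot(inherits(panel, "staging_set"))
  manual <- setdiff(panel$scorer_ids, machine)
  if (length(manual) < 2L) {
    stop("panel averages require at least 2 manual raters", call. = FALSE)
  }
  pair_vec <- function(ref_id, test_id) {
    agreement_vector(build_confusion(set_column(panel, ref_id),
                                     set_column(panel, test_id)))
  }
  average <- function(vecs) {
    mat <- do.call(cbind, vecs)
    mn <- rowMeans(mat, na.rm = TRUE)
    mn[rowSums(!is.na(mat)) == 0L] <- NA_real_
    list(mean = mn,
         n_undefined = rowSums(is.na(mat)),
         n_pairs = ncol(mat))
  }
  pairs <- expand.grid(ref = manual, test = manual,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$test, ]
  within <- average(Map(pair_vec, pairs$ref, pairs$test))
  out <- list(within = within)
  if (!is.null(machine)) {
    if (!machine %in% panel$scorer_ids) {
      stop(sprintf("machine scorer '%s' not in panel", machine),
           call. = FALSE)
    }
    out$machine <- average(lapply(manual, pair_vec, test_id = machine))
  }
  out
}

#' Render a confusion matrix with totals
#'
#' Adds row/column totals (and optionally a non-consensus row) to mirror the
#' pooled cross-tabulation layout used in validation reports.
#'
#' @param m A `confusion_matrix`.
#' @param nonconsensus Optional named integer vector of discarded
#'   non-consensus epochs per test-scorer stage.
#' @return A data frame ready for CSV export.
#' @export
confusion_table <- function(m, nonconsensus = NULL) {
  tab <- as.data.frame.matrix(unclass(m))
  if (!is.null(nonconsensus)) {
    tab <- rbind(tab, "non-consensus" = as.integer(nonconsensus[colnames(m)]))
  }
  tab$Total <- rowSums(tab)
  tab <- rbind(tab, Total = colSums(tab))
  cbind(reference = rownames(tab), tab)
}
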