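# End-to-end validation pipeline: alignment -> consensus -> agreement ->
# difference analyses -> macrostructure ICCs, each with recording-level
# bootstrap inference.

# staging_set restricted to a subset of scorer columns.
subset_scorers <- function(set, ids) {
  j <- match(ids, set$scorer_ids)
  stopifnot(!anyNA(j))
  structure(
    list(recording_id = set$recording_id, scorer_ids = ids,
         stages = set$stages[, j, drop = FALSE],
         retained_epochs = set$retained_epochs,
         n_truncated = set$n_truncated, n_u_dropped = set$n_u_dropped),
    class = "staging_set"
  )
}

# 5 x 5 x n_pairs array of ordered-pair confusion matrices for one aligned
# recording; pairs given as a data frame with ref/test scorer ids.
pair_confusion_array <- function(set, pairs) {
  lab <- sleep_stages()
  arr <- array(0L, dim = c(5L, 5L, nrow(pairs)),
               dimnames = list(lab, lab,
                               paste(pairs$ref, pairs$test, sep = "|")))
  for (i in seq_len(nrow(pairs))) {
    arr[, , i] <- unclass(build_confusion(set_column(set, pairs$ref[i]),
                                          set_column(set, pairs$test[i])))
  }
  arr
}

as_cm <- function(m) structure(m, class = c("confusion_matrix", "matrix"))

# Average agreement_vector over a set of pooled pair matrices, skipping
# undefined entries (same semantics as directional_panel_averages).
average_pair_vectors <- function(pooled, keys) {
  mat <- vapply(keys, function(k) agreement_vector(as_cm(pooled[, , k])),
                numeric(17L))
  mn <- rowMeans(mat, na.rm = TRUE)
  mn[rowSums(!is.na(mat)) == 0L] <- NA_real_
  mn
}

# Statistic factory for the paired machine-vs-panel difference analysis:
# returns machine block, panel block and their difference from one resample.
make_difference_stat <- function(machine_keys, panel_keys) {
  function(rs) {
    pooled <- Reduce(`+`, rs)
    m <- average_pair_vectors(pooled, machine_keys)
    p <- average_pair_vectors(pooled, panel_keys)
    c(stats::setNames(m, paste0("machine.", names(m))),
      stats::setNames(p, paste0("panel.", names(p))),
      stats::setNames(m - p, paste0("diff.", names(m))))
  }
}

# Statistic factory for the macrostructure ICC analysis. Each recording is
# a matrix [index x scorer]; per resample, per index, pairwise ICC(A,1)
# averages are taken machine-vs-panel and within-panel.
make_icc_stat <- function(machine_id, panel_ids, indices) {
  panel_combn <- utils::combn(panel_ids, 2L)
  function(rs) {
    arr <- simplify2array(rs)          # index x scorer x recording
    scorer_ids <- dimnames(arr)[[2]]
    out <- numeric(0)
    for (ix in indices) {
      ratings <- matrix(arr[ix, , ], nrow = length(scorer_ids),
                        dimnames = list(scorer_ids, NULL))
      m <- mean_pair_icc(ratings, cbind(machine_id, panel_ids))
      p <- if (length(panel_ids) >= 2L) {
        mean_pair_icc(ratings, t(panel_combn))
      } else {
        NA_real_
      }
      out <- c(out, stats::setNames(c(m, p, m - p),
                                    paste(c("machine", "panel", "diff"),
                                          ix, sep = ".")))
    }
    out
  }
}

# Mean ICC(A,1) over scorer pairs (rows of `pairs`); `ratings` is a
# scorer x recording matrix for one index. Undefined pairs are skipped.
mean_pair_icc <- function(ratings, pairs) {
  vals <- vapply(seq_len(nrow(pairs)), function(i) {
    icc_a1_value(cbind(ratings[pairs[i, 1L], ], ratings[pairs[i, 2L], ]))
  }, numeric(1))
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

# Long-format summary table from a bootstrap_result whose component names
# are "<block>.<statistic>".
blocks_to_table <- function(boot, diff_block = "diff") {
  parts <- strsplit(names(boot$point), ".", fixed = TRUE)
  block <- vapply(parts, `[[`, character(1), 1L)
  statistic <- vapply(parts, function(p) paste(p[-1L], collapse = "."),
                      character(1))
  sig <- ci_significance(boot$lower, boot$upper)
  data.frame(
    block = block, statistic = statistic,
    plugin = unname(boot$plugin), median = unname(boot$point),
    lower = unname(boot$lower), upper = unname(boot$upper),
    n_defined = unname(boot$n_defined),
    significant = ifelse(block == diff_block, unname(sig), NA_character_),
    stringsAsFactors = FALSE
  )
}

stats_to_table <- function(boot) {
  data.frame(
    statistic = names(boot$point),
    plugin = unname(boot$plugin), median = unname(boot$point),
    lower = unname(boot$lower), upper = unname(boot$upper),
    n_defined = unname(boot$n_defined),
    stringsAsFactors = FALSE
  )
}

#' Run the full multi-scorer validation study
#'
#' Orchestrates the whole analysis for one study: per recording, scorers
#' are aligned and `U`-epochs removed (independently for each analysis, so
#' that each analysis uses exactly the epochs staged by all scorers it
#' involves); then
#' \enumerate{
#'   \item machine vs the manual panel's majority vote: pooled confusion
#'     matrix, OPA, Cohen's kappa, per-stage PPA/NPA/PPV with bootstrap
#'     medians and 95\% CIs, and the consensus epoch accounting;
#'   \item machine vs the clinical staging (when a clinical scorer is
#'     present): same statistics;
#'   \item paired difference analysis: average machine-vs-technician
#'     agreement minus average within-technician agreement (all ordered
#'     technician pairs), per statistic, with CI-sign significance;
#'   \item the clinical analogue: machine-vs-clinical minus average
#'     technician-vs-clinical agreement;
#'   \item macrostructure reliability: per-index average pairwise ICC(A,1)
#'     machine-vs-panel and within-panel (and vs clinical), with
#'     bootstrapped differences.
#' }
#' All bootstrap runs resample whole recordings (10,000 resamples by
#' default) and are reproducible from `seed`.
#'
#' @param manifest A `study_manifest`, a path to one, or a `study_data`
#'   object from [load_study()].
#' @param n_resamples Bootstrap resamples per analysis.
#' @param seed Integer master seed; per-analysis seeds are derived from it.
#' @param out_dir Optional directory: when given, CSV tables, a JSON report
#'   and a run log are written there via [write_study_report()].
#' @return An object of class `study_report`; see [write_study_report()]
#'   for the serialised layout.
#' @export
run_validation_study <- function(manifest, n_resamples = 10000L,
                                 seed = 1L, out_dir = NULL) {
  study <- if (inherits(manifest, "study_data")) manifest
           else load_study(manifest)
  scorers <- attr(study, "scorers")
  machine <- scorers$id[scorers$role == "automatic"]
  manual <- scorers$id[scorers$role == "manual"]
  clinical <- scorers$id[scorers$role == "clinical"]
  has_clinical <- length(clinical) == 1L
  cfg <- function(offset) {
    bootstrap_config(n_resamples = n_resamples, seed = seed + offset)
  }

  # ---- per-recording preparation -------------------------------------
  acct <- list(); conf_majority <- list(); noncons_by_stage <-
    stats::setNames(rep(0L, 5L), sleep_stages())
  pair_panel <- list(); conf_clinical <- list(); pair_clin <- list()

  manual_pairs <- expand.grid(ref = manual, test = manual,
                              stringsAsFactors = FALSE)
  manual_pairs <- manual_pairs[manual_pairs$ref != manual_pairs$test, ]
  machine_pairs <- data.frame(ref = manual, test = machine,
                              stringsAsFactors = FALSE)
  panel_pairs <- rbind(machine_pairs, manual_pairs)

  for (rec_id in names(study)) {
    hyps <- study[[rec_id]]
    set <- tryCatch(align_and_filter(hyps[c(machine, manual)]),
                    hypnoagree_empty_set = function(e) NULL)
    if (is.null(set)) {
      warning(sprintf("recording %s: no retained epochs; skipped", rec_id),
              call. = FALSE)
      next
    }
    mv <- majority_vote(subset_scorers(set, manual))
    keep <- !is.na(mv$consensus)
    n_max <- max(vapply(hyps[c(machine, manual)], length, integer(1)))
    acct[[rec_id]] <- data.frame(
      recording_id = rec_id,
      n_staged_max = n_max,
      n_truncated = set$n_truncated,
      n_u_dropped = set$n_u_dropped,
      n_retained = nrow(set$stages),
      n_full = mv$n_full, n_partial = mv$n_partial,
      n_nonconsensus = mv$n_nonconsensus,
      stringsAsFactors = FALSE
    )
    machine_col <- set_column(set, machine)
    nc <- table(factor(machine_col[!keep], levels = sleep_stages()))
    noncons_by_stage <- noncons_by_stage + as.integer(nc)
    if (any(keep)) {
      conf_majority[[rec_id]] <-
        build_confusion(mv$consensus[keep], machine_col[keep])
    }
    pair_panel[[rec_id]] <- pair_confusion_array(set, panel_pairs)

    if (has_clinical) {
      set_b <- tryCatch(align_and_filter(hyps[c(machine, clinical)]),
                        hypnoagree_empty_set = function(e) NULL)
      if (!is.null(set_b)) {
        conf_clinical[[rec_id]] <-
          build_confusion(set_column(set_b, clinical),
                          set_column(set_b, machine))
      }
      set_d <- tryCatch(align_and_filter(hyps[c(machine, manual, clinical)]),
                        hypnoagree_empty_set = function(e) NULL)
      if (!is.null(set_d)) {
        clin_pairs <- data.frame(ref = clinical,
                                 test = c(machine, manual),
                                 stringsAsFactors = FALSE)
        pair_clin[[rec_id]] <- pair_confusion_array(set_d, clin_pairs)
      }
    }
  }
  if (length(conf_majority) == 0L) {
    stop("no recording yielded analysable epochs", call. = FALSE)
  }
  accounting <- do.call(rbind, acct)

  # ---- 1. machine vs majority vote -----------------------------------
  pooled_stat <- function(confs) agreement_vector(pool_confusion(confs))
  boot_majority <- cluster_bootstrap(conf_majority, pooled_stat, cfg(101L))
  pooled_majority <- pool_confusion(conf_majority)

  # ---- 2. machine vs clinical ----------------------------------------
  boot_clinical <- NULL; pooled_clinical <- NULL
  if (has_clinical && length(conf_clinical) > 0L) {
    boot_clinical <- cluster_bootstrap(conf_clinical, pooled_stat, cfg(102L))
    pooled_clinical <- pool_confusion(conf_clinical)
  }

  # ---- 3. machine-vs-panel difference --------------------------------
  machine_keys <- paste(machine_pairs$ref, machine_pairs$test, sep = "|")
  manual_keys <- paste(manual_pairs$ref, manual_pairs$test, sep = "|")
  boot_diff <- cluster_bootstrap(
    pair_panel, make_difference_stat(machine_keys, manual_keys), cfg(103L))

  # ---- 4. clinical difference ----------------------------------------
  boot_diff_clin <- NULL
  if (has_clinical && length(pair_clin) > 0L) {
    mkey <- paste(clinical, machine, sep = "|")
    tkeys <- paste(clinical, manual, sep = "|")
    boot_diff_clin <- cluster_bootstrap(
      pair_clin, make_difference_stat(mkey, tkeys), cfg(104L))
  }

  # ---- 5. macrostructure ICCs ----------------------------------------
  indices <- macro_index_names()
  macro_scorers <- c(machine, manual, clinical)
  macro_recs <- lapply(study, function(hyps) {
    vapply(macro_scorers, function(id) {
      unlist(unclass(compute_macro(hyps[[id]]))[indices])
    }, numeric(length(indices)))
  })
  macro_recs <- lapply(macro_recs, function(m) {
    rownames(m) <- indices
    m
  })
  boot_icc_panel <- cluster_bootstrap(
    macro_recs, make_icc_stat(machine, manual, indices), cfg(105L))
  boot_icc_clin <- NULL
  if (has_clinical) {
    boot_icc_clin <- cluster_bootstrap(
      macro_recs, make_icc_stat2(clinical, machine, manual, indices),
      cfg(106L))
  }

  macro_df <- macro_table(unlist(lapply(study, function(hyps) {
    hyps[macro_scorers]
  }), recursive = FALSE))
  rownames(macro_df) <- NULL

  report <- structure(
    list(
      study_id = attr(study, "study_id"),
      scorers = scorers,
      config = list(seed = seed, n_resamples = as.integer(n_resamples)),
      accounting = accounting,
      consensus = c(full = sum(accounting$n_full),
                    partial = sum(accounting$n_partial),
                    nonconsensus = sum(accounting$n_nonconsensus)),
      majority = list(
        pooled = pooled_majority,
        nonconsensus_by_stage = noncons_by_stage,
        table = confusion_table(pooled_majority, noncons_by_stage),
        stats = stats_to_table(boot_majority)
      ),
      clinical = if (!is.null(boot_clinical)) list(
        pooled = pooled_clinical,
        table = confusion_table(pooled_clinical),
        stats = stats_to_table(boot_clinical)
      ),
      panel_diff = blocks_to_table(boot_diff),
      clinical_diff = if (!is.null(boot_diff_clin))
        blocks_to_table(boot_diff_clin),
      icc_panel = blocks_to_table(boot_icc_panel),
      icc_clinical = if (!is.null(boot_icc_clin))
        blocks_to_table(boot_icc_clin),
      macro = macro_df
    ),
    class = "study_report"
  )
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

# ICC statistic for the clinical comparison: machine-vs-clinical single
# pair against the average technician-vs-clinical pair.
make_icc_stat2 <- function(clinical_id, machine_id, panel_ids, indices) {
  function(rs) {
    arr <- simplify2array(rs)
    scorer_ids <- dimnames(arr)[[2]]
    out <- numeric(0)
    for (ix in indices) {
      ratings <- matrix(arr[ix, , ], nrow = length(scorer_ids),
                        dimnames = list(scorer_ids, NULL))
      m <- mean_pair_icc(ratings, cbind(machine_id, clinical_id))
      p <- mean_pair_icc(ratings, cbind(panel_ids, clinical_id))
      out <- c(out, stats::setNames(c(m, p, m - p),
                                    paste(c("machine", "panel", "diff"),
                                          ix, sep = ".")))
    }
    out
  }
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("validation study report: %s\n", x$study_id))
  cat(sprintf("  %d recordings, seed %d, %d bootstrap resamples\n",
              nrow(x$accounting), x$config$seed, x$config$n_resamples))
  tot <- sum(x$consensus)
  cat(sprintf(
    "  consensus: %.2f%% full, %.2f%% partial, %.2f%% non-consensus\n",
    100 * x$consensus[["full"]] / tot,
    100 * x$consensus[["partial"]] / tot,
    100 * x$consensus[["nonconsensus"]] / tot))
  s <- x$majority$stats
  opa <- s[s$statistic == "opa", ]
  kap <- s[s$statistic == "kappa", ]
  cat(sprintf(
    "  machine vs majority: OPA %.2f%% (95%% CI %.2f-%.2f), kappa %.4f (%.4f-%.4f)\n",
    100 * opa$median, 100 * opa$lower, 100 * opa$upper,
    kap$median, kap$lower, kap$upper))
  d <- x$panel_diff
  sig <- d[d$block == "diff" & !is.na(d$significant) &
           d$significant != "none", ]
  if (nrow(sig) > 0) {
    cat("  significant machine-vs-panel differences:",
        paste(sprintf("%s (%s)", sig$statistic, sig$significant),
              collapse = ", "), "\n")
  } else {
    cat("  no significant machine-vs-panel differences\n")
  }
  invisible(x)
}

# round percent-scale statistics to 2 decimals, kappa/ICC to 4, for the
# CSV tables (the JSON report keeps full precision).
format_stats_table <- function(df, icc = FALSE) {
  fmt_row <- function(stat, v) {
    ifelse(rep(icc, length(v)) | grepl("kappa", stat),
           round(v, 4),
           round(100 * v, 2))
  }
  for (col in intersect(c("plugin", "median", "lower", "upper"),
                        names(df))) {
    df[[col]] <- fmt_row(df$statistic, df[[col]])
  }
  df
}

#' Write a study report to disk
#'
#' Writes one CSV per result table (pooled confusion matrices, agreement
#' statistics, difference analyses, ICC tables, per-recording epoch
#' accounting and macrostructure indices), a machine-readable
#' `report.json` with full precision, and a short run log. CSV statistics
#' are printed as percentages to 2 decimal places, kappa and ICC to 4.
#'
#' @param report A `study_report` from [run_validation_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE,
                     quote = FALSE, na = "")
  }
  wcsv(report$accounting, "epoch_accounting.csv")
  wcsv(report$majority$table, "confusion_majority.csv")
  wcsv(format_stats_table(report$majority$stats), "stats_majority.csv")
  wcsv(format_stats_table(report$panel_diff), "diff_panel.csv")
  wcsv(format_stats_table(report$icc_panel, icc = TRUE), "icc_panel.csv")
  wcsv(report$macro, "macro_indices.csv")
  if (!is.null(report$clinical)) {
    wcsv(report$clinical$table, "confusion_clinical.csv")
    wcsv(format_stats_table(report$clinical$stats), "stats_clinical.csv")
  }
  if (!is.null(report$clinical_diff)) {
    wcsv(format_stats_table(report$clinical_diff), "diff_clinical.csv")
  }
  if (!is.null(report$icc_clinical)) {
    wcsv(format_stats_table(report$icc_clinical, icc = TRUE), "icc_clinical.csv")
  }
  json <- report
  json$majority$pooled <- unclass(json$majority$pooled)
  if (!is.null(json$clinical)) {
    json$clinical$pooled <- unclass(json$clinical$pooled)
  }
  jsonlite::write_json(unclass(json), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  log <- c(
    sprintf("study: %s", report$study_id),
    sprintf("generated: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("seed: %d, resamples: %d", report$config$seed,
            report$config$n_resamples),
    sprintf("recordings analysed: %d", nrow(report$accounting)),
    apply(report$accounting, 1L, function(r) {
      sprintf("  %s: %s staged, %s truncated, %s U-dropped, %s non-consensus",
              r[["recording_id"]], r[["n_staged_max"]], r[["n_truncated"]],
              r[["n_u_dropped"]], r[["n_nonconsensus"]])
    })
  )
  writeLines(log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
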