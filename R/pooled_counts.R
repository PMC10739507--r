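# Published pooled cross-tabulations bundled for benchmarking.

#' Pooled epoch cross-tabulations from a published validation study
#'
#' Epoch counts reported by a multi-center validation study of an EEG-based
#' automatic sleep scorer on 40 overnight clinical recordings, scored
#' independently by three experienced technicians and, separately, during
#' clinical practice. Two pooled cross-tabulations are available:
#' \describe{
#'   \item{`"majority"`}{automatic scorer (columns) against the three
#'     technicians' majority-vote staging (rows), with the row of epochs
#'     discarded for lack of consensus and the consensus accounting (full /
#'     partial / non-consensus epoch counts).}
#'   \item{`"clinical"`}{automatic scorer (columns) against the staging
#'     performed during clinical practice (rows).}
#' }
#' The study reported bootstrap medians (10,000 recording-level resamples)
#' as point estimates; those printed medians are included for comparison
#' with the pooled plug-in statistics this package computes from the
#' counts.
#'
#' @param analysis `"majority"` or `"clinical"`.
#' @return List with components:
#'   \describe{
#'     \item{counts}{5x5 `confusion_matrix` of retained epochs}
#'     \item{nonconsensus}{(majority only) named vector: discarded
#'       non-consensus epochs per automatic-scorer stage}
#'     \item{consensus_counts}{(majority only) named vector `full`,
#'       `partial`, `nonconsensus`}
#'     \item{printed}{list of the study's printed bootstrap medians:
#'       `opa_pct`, `kappa`, and per-stage `ppa_pct`, `npa_pct`, `ppv_pct`}
#'   }
#' @export
#' @examples
#' m <- published_pooled_counts("majority")
#' overall_percent_agreement(m$counts)
published_pooled_counts <- function(analysis = c("majority", "clinical")) {
  analysis <- match.arg(analysis)
  lab <- sleep_stages()
  as_cm <- function(cells) {
    structure(matrix(as.integer(cells), 5L, 5L, byrow = TRUE,
                     dimnames = list(reference = lab, test = lab)),
              class = c("confusion_matrix", "matrix"))
  }
  if (analysis == "majority") {
    list(
      counts = as_cm(c(
        6478,  902,   190,   10,   37,
         174, 1501,   879,    1,  176,
          59,  636, 12888,  559,  221,
           5,    0,   539, 5412,    0,
          14,   61,   239,    0, 4556)),
      nonconsensus = c(W = 48L, N1 = 201L, N2 = 144L, N3 = 21L, R = 79L),
      consensus_counts = c(full = 26963L, partial = 8574L,
                           nonconsensus = 493L),
      printed = list(
        opa_pct = 86.78, kappa = 0.8205,
        ppa_pct = c(W = 85.11, N1 = 54.90, N2 = 89.78, N3 = 90.90,
                    R = 93.69),
        npa_pct = c(W = 99.10, N1 = 95.15, N2 = 91.28, N3 = 98.11,
                    R = 98.60),
        ppv_pct = c(W = 96.26, N1 = 48.47, N2 = 87.49, N3 = 90.69,
                    R = 91.36),
        row_totals = c(W = 7617L, N1 = 2731L, N2 = 14363L, N3 = 5956L,
                       R = 4870L),
        col_totals = c(W = 6778L, N1 = 3301L, N2 = 14879L, N3 = 6003L,
                       R = 5069L),
        grand_total = 36030L
      )
    )
  } else {
    list(
      counts = as_cm(c(
        6410, 1067,   307,   20,   56,
         316, 1343,   808,    4,  157,
          89,  797, 12659,  677,  328,
           4,    0,   770, 5302,    0,
          18,   95,   357,    0, 4528)),
      printed = list(
        opa_pct = 83.74, kappa = 0.7796,
        ppa_pct = c(W = 81.61, N1 = 50.98, N2 = 87.03, N3 = 87.32,
                    R = 90.71),
        npa_pct = c(W = 98.50, N1 = 94.18, N2 = 89.63, N3 = 97.70,
                    R = 98.28),
        ppv_pct = c(W = 93.78, N1 = 40.69, N2 = 84.98, N3 = 88.40,
                    R = 89.43),
        row_totals = c(W = 7860L, N1 = 2628L, N2 = 14550L, N3 = 6076L,
                       R = 4998L),
        col_totals = c(W = 6837L, N1 = 3302L, N2 = 14901L, N3 = 6003L,
                       R = 5069L),
        grand_total = 36112L
      )
    )
  }
}
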