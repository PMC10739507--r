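# hypnoagree

Validation statistics for automatic sleep staging against multiple human
scorers.

## The problem

Overnight polysomnography is staged in 30-second epochs, each labelled
wake (W), N1, N2, N3 or REM (R), with an unclassified code (U) for
epochs too corrupted to score. Automatic scorers are validated against
human experts, but human scoring itself disagrees at the 80–85% level,
so a credible validation needs more than a single accuracy number: it
needs consensus references, chance-corrected and per-stage agreement,
a way to ask *"is the machine better or worse than a human scorer?"*
directly, and inference that respects the fact that epochs within a
recording are highly dependent.

`hypnoagree` implements that methodology end to end for studies with
one automatic scorer, a panel of manual scorers (typically three
technicians), and optionally the staging performed during clinical
practice:

* **Alignment and retention** — scorers may stop staging a few epochs
  before the end of a recording; sequences are truncated to the common
  length and every epoch with a U from any scorer in the analysis is
  removed.
* **Majority-vote consensus** — an epoch's reference stage is the one
  at least two of three technicians assigned; complete-disagreement
  epochs are discarded (and accounted for).
* **Agreement statistics** on pooled confusion matrices: overall
  percent agreement `OPA = trace/N`, Cohen's kappa
  `κ = (p_o − p_e)/(1 − p_e)`, and per-stage PPA (sensitivity), NPA
  (specificity) and PPV.
* **Directional machine-vs-panel comparison** — because agreement of A
  referenced on B differs from B referenced on A, the within-panel
  reference value averages all six ordered technician pairs, while the
  machine is always the test scorer against each technician; the paired
  difference of the two averages answers the better-or-worse question
  on *all* staged epochs, including the non-consensus ones.
* **Macrostructure reliability** — TST, SL, REML, SE, WASO and time in
  each stage per scorer, compared across scorers with the
  absolute-agreement single-measure intraclass correlation
  `ICC(A,1) = (MSR − MSE) / (MSR + (k−1)MSE + (k/n)(MSC − MSE))`,
  averaged over scorer pairs and interpreted on the standard
  poor/moderate/good/excellent bands.
* **Cluster bootstrap** — every point estimate is the median of 10,000
  recording-level (not epoch-level) resamples with a 2.5–97.5 percentile
  CI; a difference is significant when both CI bounds share a sign.
* **Synthetic cohorts** — a first-order Markov sleep-process model plus
  per-rater confusion-matrix mis-scoring (with U injection and
  end-of-recording truncation) generates full multi-rater studies on
  disk, so the entire pipeline is testable without proprietary PSG data.

## Worked example

```r
library(hypnoagree)

dir <- tempfile()
manifest <- simulate_study(dir, n_recordings = 8, seed = 1)
report <- run_validation_study(manifest, n_resamples = 2000, seed = 1)
report
#> validation study report: synthetic-1
#>   8 recordings, seed 1, 2000 bootstrap resamples
#>   consensus: 74.76% full, 23.71% partial, 1.53% non-consensus
#>   machine vs majority: OPA 90.52% (95% CI 89.73-91.19), kappa 0.8686 (0.8570-0.8778)
#>   significant machine-vs-panel differences: ppa_N2 (positive), ppa_R (negative)
```

Reading this: of all retained epochs, 74.76% had unanimous technician
agreement and 1.53% had no majority at all (those epochs are excluded
from the machine-vs-majority comparison). The machine agrees with the
majority-vote reference on 90.52% of epochs (kappa 0.87, i.e. far above
chance). In the direct paired comparison at this small cohort size, the
machine's N2 sensitivity is significantly above the technicians'
within-panel average and its REM sensitivity significantly below; all
other statistics are statistically indistinguishable from human-level
scoring. Macrostructure reliability is summarised the same way, e.g.

```r
s <- report$icc_panel
s[s$block != "diff" & s$statistic == "tst", c("block", "median", "lower", "upper")]
#>     block    median     lower     upper
#> 1 machine 0.9909716 0.9612603 0.9978353
#> 2   panel 0.9945139 0.9784988 0.9980880
```

— total-sleep-time ICC(A,1) of machine-vs-technicians and among the
technicians, both excellent. `write_study_report(report, "out/")`
exports every table (confusion matrices with totals, agreement and
difference tables with CIs and significance flags, ICC tables, epoch
accounting, per-scorer macro indices) as CSV plus a full-precision
`report.json` and a run log. The same pipeline runs from a shell via
`inst/scripts/hypnoagree-cli.R` (`simulate` and `validate` verbs).

Real studies are consumed the same way: one `epoch_index,stage` CSV per
recording per scorer and a YAML manifest naming scorer roles and lights
times (see `?read_study_manifest`).

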