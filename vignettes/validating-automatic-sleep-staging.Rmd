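---
title: "Validating an automatic sleep scorer against multiple human scorers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating an automatic sleep scorer against multiple human scorers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypnoagree)
```

## The validation problem

Sleep staging assigns one of five stages — W, N1, N2, N3, R — to every
30-second epoch of an overnight recording, between lights-off and
lights-on. There is no perfect reference: expert scorers following the
same clinical rules agree on only roughly 80–85% of epochs, and the
hardest epochs (stage transitions, N1, artefact-laden signal) are
exactly where scorers disagree with each other *and* where an automatic
scorer is most likely to err. A sound validation of an automatic scorer
therefore runs several complementary analyses, all implemented here:

1. agreement of the machine with a **majority-vote consensus** of a
   technician panel (the conventional regulatory benchmark);
2. agreement of the machine with the **clinical staging** that was
   produced in routine practice;
3. a **direct machine-vs-human comparison**: the machine's average
   agreement with the technicians minus the technicians' average
   agreement among themselves, which removes the flattery inherent in
   scoring against a consensus that discards the hardest epochs;
4. **macrostructure reliability**: whether summary indices clinicians
   actually act on (total sleep time, latencies, efficiency, WASO,
   stage times) are reproduced at human-level reliability.

## Data model and retention rules

Input is one per-epoch stage sequence per scorer per recording
(`epoch_index,stage` CSV, a YAML manifest carrying scorer roles and
lights times). Two retention rules are applied per analysis, i.e. using
exactly the scorers that analysis involves:

* **End truncation.** Scorers blinded to the lights-on time rarely stop
  staging at the same epoch; all sequences are truncated to the common
  (minimum) staged length. Truncation is end-only: every scorer starts
  at lights-off, so epoch `i` means the same clock time for all.
* **U removal.** Any epoch in which at least one scorer of the analysis
  assigned the unclassified stage is dropped. The retained matrix
  contains five-stage calls only, and the per-recording accounting
  (`retained + truncated + U-dropped = longest input`) is asserted in
  the test suite and reported in the run log.

## Consensus and agreement statistics

The majority vote assigns the stage chosen by at least two of three
technicians; epochs where all three disagree are non-consensus and are
discarded from the machine-vs-majority analysis (with full, partial and
non-consensus counts reported, since the non-consensus rate is itself a
quality indicator of the panel). For panels larger than three, a tie at
the top vote count is conservatively treated as non-consensus.

All epoch-level statistics are computed on epochs pooled across
recordings (micro-average), matching how validation tables are
conventionally printed; the pooled confusion matrix is the elementwise
sum of per-recording matrices, which is also what makes recording-level
resampling cheap. From a matrix with reference scorer on rows:

* `OPA = trace / N`;
* Cohen's `kappa = (po - pe) / (1 - pe)`, `NA` (never silently zero)
  when both scorers are constant and identical so that `pe = 1`;
* per stage *s*: `PPA = TP / ref_s`, `NPA = (N - ref_s - test_s + TP) /
  (N - ref_s)`, `PPV = TP / test_s`, each `NA` when its denominator is
  zero. Undefined values propagate as missing and are skipped (and
  counted) by every average, because coercing them to zero would bias
  panel averages downward.

The direct comparison is deliberately **directional**. Within the
panel, every ordered technician pair contributes (six values for three
technicians: PPA of A referenced on B is the PPV of B referenced on A,
so averaging both orders makes the within-panel average PPA equal the
average PPV — a useful internal consistency check). The machine always
enters as the *test* scorer with each technician as reference, and the
reverse direction is not averaged in: the question is how well the
machine reproduces human staging, not the converse. The difference of
the two averages is evaluated on all staged epochs, non-consensus ones
included.

## Macrostructure indices

Indices are computed per scorer from that scorer's own full hypnogram
(0.5 min per epoch): sleep onset is the first epoch of any sleep stage;
`SL` is the time from lights-off to onset; `TST` the time in
N1/N2/N3/R; `WASO` all wake after onset including terminal wake;
`REML` the time from onset to the first R epoch; `SE = 100·TST/TIB`.
Unclassified epochs count toward time in bed, toward latency if before
onset and toward WASO if after — so `SL + TST + WASO = TIB` holds
exactly whenever onset exists, an identity the property tests assert on
thousands of random hypnograms. On recordings with no sleep epoch (or
no REM epoch) the affected latencies are *missing*, not zero: a zero
latency would fabricate agreement between scorers. Reliability uses
`ICC(A,1)` — absolute agreement, single measures, two-way layout —
computed from the ANOVA mean squares without replication; rows with a
missing value in either scorer of a pair are dropped with a count.
Pairwise (k = 2) ICCs are averaged: machine against each technician,
and all unordered technician pairs (the ICC is symmetric, so ordered
averaging would change nothing). Interpretation bands are poor < 0.5 ≤
moderate < 0.75 ≤ good < 0.9 ≤ excellent, with 0.9 itself assigned to
excellent — the bands are conventionally quoted with open boundaries,
so the half-open convention here is stated explicitly and applied
consistently.

## Bootstrap inference

Epochs within a recording are strongly autocorrelated, so all
uncertainty comes from a **cluster bootstrap over whole recordings**:
10,000 resamples by default, each drawing `n` recordings with
replacement and re-evaluating the statistic on the pooled resample. The
point estimate is the resample median, the 95% CI the 2.5th/97.5th
linear-interpolation percentiles (the plug-in value is reported
alongside). Differences are **paired**: one resample drives both sides,
which is what makes the CI-sign significance rule (significant iff both
bounds share a sign) meaningful; independent resampling would inflate
the difference variance. Resamples where a statistic is undefined (a
stage absent from every resampled recording, or fewer than two complete
ICC rows) are dropped from that statistic's distribution with a
reported count — imputation would require a model the data do not
support. Every run is reproducible from one integer seed; the pipeline
derives a fixed per-analysis offset from it.

## The synthetic cohort generator

Because clinical multi-scorer staging data are rarely shareable, the
generator produces full studies with the statistical structure the
analyses assume. The latent sleep process is a first-order Markov chain
over the five stages; the default transition matrix gives sticky stages
with realistic bout structure and long-run occupancy of roughly 20% W,
8% N1, 40% N2, 17% N3, 15% R, recordings of 720–1080 epochs (6–9 h in
bed) starting from wake at a jittered lights-off near 22:20. Raters
mis-score each epoch independently through a row-stochastic confusion
matrix, may emit U with a small probability, and may leave a few
trailing epochs unstaged.

The default panel encodes the study conditions of a published
multi-center validation of an EEG-based automatic scorer: 40
recordings; three technicians with symmetric error rate 0.092, which
yields a three-rater full-consensus rate of `(1-ε)³ + 4(ε/4)³ ≈ 74.9%`
and a within-panel average OPA of `(1-ε)² + ε²/4 ≈ 82.7%`; machine and
clinical scorer at 0.085, putting the machine-vs-technician average OPA
near 83.3%; clinical U probability `1e-4`; technician truncation
uniform on 0–3 epochs. These closed forms are verified against
simulation in the test suite, and the simulated rater's confusion
matrix is recovered from pooled counts as a parameter-recovery check.

What the generator does **not** emulate: rater errors correlated across
raters or concentrated on genuinely ambiguous epochs (real technicians
disagree on the *same* hard epochs), semi-Markov dwell times and
ultradian cycling, and any signal-level artefact structure. The main
visible consequence is that a synthetic machine-vs-majority OPA exceeds
what studies report on real data at matched single-pair agreement,
because an independent-error majority vote is a better reference than a
correlated-error one. Passing pipeline tests on synthetic cohorts
therefore demonstrates the correctness of the statistical machinery
under its stated assumptions, not field performance of any scorer.

## Numerical and design choices

* Epoch duration is fixed at 30 s; macro arithmetic depends on it.
* Stage tokens are resolved case-insensitively through an alias table
  (`Wake/W/0`, `N1/1`, …, `REM/R/5`, `U/?/9`); unknown tokens, gaps or
  empty files are hard errors naming the offending token and line.
* Percentile method with R's type-7 (linear interpolation) quantiles;
  the median of an even number of resamples is the midpoint of the two
  central order statistics.
* Kappa's degenerate case uses an exact-arithmetic guard
  (`1 - pe < 1e-14`); the ICC denominator is compared to zero relative
  to the magnitude of the mean squares.
* Bundled published pooled counts (`published_pooled_counts()`) carry
  the printed bootstrap medians for comparison; plug-in ratios of
  pooled counts and bootstrap medians are distinct estimators and are
  labelled as such wherever both appear.
* Problem sizes in the test suite are chosen to make Monte-Carlo error
  comfortably smaller than the asserted tolerances: 50,000 epochs for
  confusion recovery (per-cell binomial SD below 0.005 against a 0.01
  band), 5,000 subjects for ICC variance-component recovery (estimator
  SD well below the 0.02 band), 500 cohorts of 40 recordings at 1,000
  resamples for CI coverage (binomial SD just under 1 percentage point
  against a 92–98% band).

## Known limitations

* Independent rater errors understate between-rater agreement
  correlation; significance findings on synthetic cohorts are
  consequently anti-conservative relative to real panels.
* Only pairwise Cohen's kappa is provided (no Fleiss or multi-rater
  chance correction), matching the pairwise design of the difference
  analysis.
* ICC confidence intervals come from the cluster bootstrap, not from
  F-distribution theory, and only the (A,1) single-measure definition
  is implemented.
* The pipeline reads plain-text hypnograms; it deliberately knows
  nothing about EDF signals or scoring rules — producing the per-epoch
  stage calls is upstream of this package.
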