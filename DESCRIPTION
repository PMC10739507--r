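Package: hypnoagree
Title: Validation Statistics for Automatic Sleep Staging Against Multiple
    Human Scorers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for validating an automatic epoch-by-epoch sleep
    scorer against panels of human scorers: hypnogram alignment and
    unclassified-epoch retention rules, majority-vote consensus staging,
    pooled confusion matrices with overall percent agreement, Cohen's
    kappa and per-stage positive/negative percent agreement and positive
    predictive values, directional machine-vs-panel difference analyses,
    sleep macrostructure indices with ICC(A,1) absolute-agreement
    reliability, recording-level (cluster) bootstrap percentile inference,
    and a Markov-chain synthetic multi-rater cohort generator for
    exercising the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
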