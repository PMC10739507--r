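# Shared fixture builders for the test suite.

hyp <- function(stages, rec = "rec01", scorer = "s1") {
  hypnogram(stages, rec, scorer)
}

random_stages <- function(n, include_u = FALSE) {
  pool <- if (include_u) c(sleep_stages(), "U") else sleep_stages()
  sample(pool, n, replace = TRUE)
}

# Random 5x5 confusion matrix with strictly positive expected marginals.
random_confusion_counts <- function(n = 200L) {
  ref <- random_stages(n)
  test <- random_stages(n)
  build_confusion(ref, test)
}

# Write a hypnogram CSV with arbitrary raw tokens (to exercise parsing).
write_raw_hypnogram <- function(tokens, path,
                                indices = seq_along(tokens) - 1L) {
  writeLines(c("epoch_index,stage",
               paste(indices, tokens, sep = ",")), path)
  path
}

# A tiny in-memory study: machine + 3 technicians (+ optional clinical),
# identical error structure, for pipeline tests.
tiny_study_dir <- function(n_recordings = 4L, seed = 11L,
                           machine_eps = 0.08, tech_eps = 0.1,
                           clinical = TRUE, epochs = c(80L, 120L)) {
  raters <- list(
    machine = rater_model(symmetric_confusion(machine_eps)),
    tech1 = rater_model(symmetric_confusion(tech_eps), truncation_max = 2L),
    tech2 = rater_model(symmetric_confusion(tech_eps), truncation_max = 2L),
    tech3 = rater_model(symmetric_confusion(tech_eps), truncation_max = 2L)
  )
  roles <- c(machine = "automatic", tech1 = "manual", tech2 = "manual",
             tech3 = "manual")
  if (clinical) {
    raters$clinical <- rater_model(symmetric_confusion(tech_eps),
                                   u_prob = 0.002)
    roles <- c(roles, clinical = "clinical")
  }
  attr(raters, "roles") <- roles
  dir <- tempfile("study")
  simulate_study(dir, model = sleep_model(epochs_range = epochs),
                 raters = raters, n_recordings = n_recordings, seed = seed)
}
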