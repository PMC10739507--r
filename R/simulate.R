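# Synthetic multi-rater hypnogram cohorts.
#
# The generator emulates the structure the validation statistics assume: a
# latent "true" hypnogram per recording (first-order Markov chain over the
# five stages across the lights window), independently mis-scored by each
# rater through a per-rater confusion matrix, with optional unclassified
# (U) calls and a few unstaged epochs at the end of the recording (raters
# blinded to lights-on tend to stop a little early or late relative to one
# another).

#' Markov model of the latent sleep process
#'
#' @param initial_probs Named length-5 probability vector over
#'   [sleep_stages()] for the first epoch after lights-off.
#' @param transition 5x5 row-stochastic matrix of epoch-to-epoch stage
#'   transition probabilities (rows and columns in [sleep_stages()] order).
#' @param epochs_range Integer range (min, max) of staged epochs per
#'   recording; drawn uniformly. The default 720-1080 epochs corresponds to
#'   in-bed durations of 6-9 h, typical of overnight clinical studies.
#' @param lights_off Nominal lights-off clock time, `"HH:MM:SS"`.
#' @param lights_off_jitter_min Uniform jitter (plus/minus, minutes) on the
#'   nominal lights-off time, rounded to the 30-s grid.
#' @return A `sleep_model` list.
#' @export
sleep_model <- function(initial_probs = default_initial_probs(),
                        transition = default_transition_matrix(),
                        epochs_range = c(720L, 1080L),
                        lights_off = "22:20:00",
                        lights_off_jitter_min = 25) {
  transition <- as.matrix(transition)
  stopifnot(length(initial_probs) == 5L,
            all(dim(transition) == c(5L, 5L)),
            all(initial_probs >= 0), all(transition >= 0),
            length(epochs_range) == 2L,
            epochs_range[1] >= 1L, epochs_range[1] <= epochs_range[2])
  if (abs(sum(initial_probs) - 1) > 1e-12) {
    stop("initial_probs must sum to 1", call. = FALSE)
  }
  if (any(abs(rowSums(transition) - 1) > 1e-12)) {
    stop("transition matrix rows must sum to 1", call. = FALSE)
  }
  structure(
    list(initial_probs = initial_probs / sum(initial_probs),
         transition = transition / rowSums(transition),
         epochs_range = as.integer(epochs_range),
         lights_off = lights_off,
         lights_off_jitter_min = lights_off_jitter_min),
    class = "sleep_model"
  )
}

#' Default initial stage distribution
#'
#' Recordings start at lights-off, almost always awake.
#' @return Named probability vector over the five stages.
#' @export
default_initial_probs <- function() {
  c(W = 0.90, N1 = 0.08, N2 = 0.02, N3 = 0, R = 0)
}

#' Default stage transition matrix
#'
#' A first-order chain whose long-run stage occupancy is close to the mix
#' seen in overnight clinical cohorts (roughly 20\% wake, 8\% N1, 40\% N2,
#' 17\% N3, 15\% REM) with sticky stages giving realistic bout lengths.
#' @return 5x5 row-stochastic matrix.
#' @export
default_transition_matrix <- function() {
  m <- matrix(c(
    # to:   W     N1     N2     N3     R
    0.850, 0.120, 0.025, 0.000, 0.005,  # from W
    0.120, 0.450, 0.400, 0.005, 0.025,  # from N1
    0.025, 0.020, 0.870, 0.060, 0.025,  # from N2
    0.015, 0.005, 0.130, 0.850, 0.000,  # from N3
    0.030, 0.030, 0.030, 0.000, 0.910   # from R
  ), nrow = 5L, byrow = TRUE,
  dimnames = list(sleep_stages(), sleep_stages()))
  m
}

#' Rater mis-scoring model
#'
#' Per epoch, independently of other epochs and raters: with probability
#' `u_prob` the rater reports `U`; otherwise the reported stage is drawn
#' from the confusion row of the true stage. Finally a uniform
#' 0..`truncation_max` number of epochs is left unstaged at the end of the
#' recording.
#'
#' @param confusion 5x5 row-stochastic matrix, rows = true stage, columns =
#'   reported stage, in [sleep_stages()] order.
#' @param u_prob Probability of reporting `U` on any epoch (default 0).
#' @param truncation_max Maximum number of trailing epochs left unstaged
#'   (default 0; the draw is uniform on 0..`truncation_max`).
#' @return A `rater_model` list.
#' @export
rater_model <- function(confusion = symmetric_confusion(0.1),
                        u_prob = 0, truncation_max = 0L) {
  confusion <- as.matrix(confusion)
  stopifnot(all(dim(confusion) == c(5L, 5L)), all(confusion >= 0),
            u_prob >= 0, u_prob < 1, truncation_max >= 0L)
  if (any(abs(rowSums(confusion) - 1) > 1e-12)) {
    stop("confusion matrix rows must sum to 1", call. = FALSE)
  }
  structure(
    list(confusion = confusion / rowSums(confusion),
         u_prob = u_prob,
         truncation_max = as.integer(truncation_max)),
    class = "rater_model"
  )
}

#' Symmetric-error confusion matrix
#'
#' Diagonal `1 - eps`, with the error mass `eps` split evenly over the four
#' other stages. Under this model the expected rater-vs-truth overall
#' agreement is exactly `1 - eps`.
#'
#' @param eps Per-epoch mis-scoring probability.
#' @return 5x5 row-stochastic matrix.
#' @export
symmetric_confusion <- function(eps) {
  stopifnot(eps >= 0, eps < 1)
  m <- matrix(eps / 4, 5L, 5L,
              dimnames = list(sleep_stages(), sleep_stages()))
  diag(m) <- 1 - eps
  m
}

#' Default rater panel for a simulated validation study
#'
#' One automatic scorer, three manual technicians and one clinical scorer,
#' with symmetric per-epoch error rates chosen so that the cohort
#' reproduces the agreement structure of multi-scorer validation studies:
#' technicians at eps = 0.092 give a three-rater full-consensus rate of
#' about 74.9\% and a within-panel average OPA of about 82.7\%; the machine
#' at eps = 0.085 (slightly more accurate than an individual technician)
#' gives a machine-vs-technician average OPA of about 83.3\%; the clinical
#' scorer at eps = 0.085 carries a small unclassified-epoch probability.
#' Technicians, blinded to lights times, leave up to 3 trailing epochs
#' unstaged.
#'
#' @return Named list of [rater_model()] objects with a `roles` attribute
#'   mapping scorer id to `"automatic"`, `"manual"` or `"clinical"`.
#' @export
default_rater_panel <- function() {
  panel <- list(
    machine = rater_model(symmetric_confusion(0.085)),
    tech1 = rater_model(symmetric_confusion(0.092), truncation_max = 3L),
    tech2 = rater_model(symmetric_confusion(0.092), truncation_max = 3L),
    tech3 = rater_model(symmetric_confusion(0.092), truncation_max = 3L),
    clinical = rater_model(symmetric_confusion(0.085), u_prob = 1e-4)
  )
  attr(panel, "roles") <- c(machine = "automatic",
                            tech1 = "manual", tech2 = "manual",
                            tech3 = "manual", clinical = "clinical")
  panel
}

# -- clock-time helpers (seconds since midnight, wrap past 24 h) ----------

parse_clock <- function(s) {
  p <- as.integer(strsplit(s, ":", fixed = TRUE)[[1L]])
  p[1L] * 3600L + p[2L] * 60L + p[3L]
}

format_clock <- function(sec) {
  sec <- sec %% 86400L
  sprintf("%02d:%02d:%02d", sec %/% 3600L, (sec %% 3600L) %/% 60L,
          sec %% 60L)
}

#' Simulate latent true hypnograms
#'
#' Draws `n_recordings` first-order Markov stage sequences from a
#' [sleep_model()]. Deterministic under a fixed seed; recording ids are
#' assigned sequentially (`rec01`, `rec02`, ...).
#'
#' @param model A [sleep_model()].
#' @param n_recordings Number of recordings.
#' @param seed Optional integer seed.
#' @return List of [hypnogram()] objects with scorer id `"truth"`.
#' @export
simulate_truth <- function(model, n_recordings, seed = NULL) {
  stopifnot(inherits(model, "sleep_model"), n_recordings >= 1L)
  if (!is.null(seed)) set.seed(seed)
  stages <- sleep_stages()
  lapply(seq_len(n_recordings), function(r) {
    n_ep <- sample.int(model$epochs_range[2] - model$epochs_range[1] + 1L,
                       1L) + model$epochs_range[1] - 1L
    s <- integer(n_ep)
    s[1L] <- sample.int(5L, 1L, prob = model$initial_probs)
    for (t in seq_len(n_ep - 1L)) {
      s[t + 1L] <- sample.int(5L, 1L, prob = model$transition[s[t], ])
    }
    jitter <- round(stats::runif(1, -model$lights_off_jitter_min,
                                 model$lights_off_jitter_min) * 2) / 2
    off <- parse_clock(model$lights_off) + as.integer(jitter * 60)
    hypnogram(stages[s],
              recording_id = sprintf("rec%02d", r),
              scorer_id = "truth",
              lights_off = format_clock(off),
              lights_on = format_clock(off + n_ep * EPOCH_SECONDS))
  })
}

#' Simulate one rater's scoring of a true hypnogram
#'
#' @param truth A [hypnogram()] of true stages (no `U`).
#' @param rater A [rater_model()].
#' @param scorer_id Scorer id for the output.
#' @param seed Optional integer seed (usually inherited from the cohort
#'   generator's stream).
#' @return A [hypnogram()] of the rater's reported stages.
#' @export
simulate_rater <- function(truth, rater, scorer_id, seed = NULL) {
  stopifnot(inherits(truth, "hypnogram"), inherits(rater, "rater_model"))
  if (!is.null(seed)) set.seed(seed)
  true_idx <- match(truth$stages, sleep_stages())
  stopifnot(!anyNA(true_idx))
  n <- length(true_idx)
  # cumulative-probability inversion, one uniform per epoch
  cum <- t(apply(rater$confusion, 1L, cumsum))
  cum[, 5L] <- 1  # guard against floating-point undershoot in the last bin
  u <- stats::runif(n)
  rep_idx <- max.col(cum[true_idx, , drop = FALSE] >= u, "first")
  reported <- sleep_stages()[rep_idx]
  if (rater$u_prob > 0) {
    reported[stats::runif(n) < rater$u_prob] <- stage_unscored()
  }
  if (rater$truncation_max > 0L) {
    drop <- sample.int(rater$truncation_max + 1L, 1L) - 1L
    if (drop >= n) drop <- n - 1L
    reported <- reported[seq_len(n - drop)]
  }
  hypnogram(reported, truth$recording_id, scorer_id,
            truth$lights_off, truth$lights_on)
}

#' Simulate an in-memory multi-rater cohort
#'
#' @param model A [sleep_model()].
#' @param raters Named list of [rater_model()] objects (see
#'   [default_rater_panel()]).
#' @param n_recordings Number of recordings (default 40, the size of a
#'   typical device-validation cohort).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return List of class `sleep_cohort`: per recording, a list with `truth`
#'   (the latent hypnogram) and `scorers` (named list of rater hypnograms);
#'   the rater `roles` attribute is carried over.
#' @export
simulate_cohort <- function(model = sleep_model(),
                            raters = default_rater_panel(),
                            n_recordings = 40L, seed = 1L) {
  stopifnot(length(names(raters)) == length(raters),
            all(nzchar(names(raters))))
  set.seed(seed)
  truths <- simulate_truth(model, n_recordings)
  cohort <- lapply(truths, function(tr) {
    scorers <- lapply(names(raters), function(id) {
      simulate_rater(tr, raters[[id]], scorer_id = id)
    })
    names(scorers) <- names(raters)
    list(truth = tr, scorers = scorers)
  })
  structure(cohort, class = "sleep_cohort",
            roles = attr(raters, "roles"), seed = seed)
}

#' Write a simulated study to disk in the pipeline's file layout
#'
#' Produces one hypnogram CSV per recording per scorer plus a YAML study
#' manifest, the exact inputs [run_validation_study()] consumes.
#'
#' @param dir Output directory (created if needed).
#' @param model,raters,n_recordings,seed As in [simulate_cohort()].
#' @param roles Named character vector mapping scorer id to role
#'   (`"automatic"`, `"manual"`, `"clinical"`); defaults to the `roles`
#'   attribute of `raters`.
#' @return Path to the written manifest file, invisibly.
#' @export
simulate_study <- function(dir, model = sleep_model(),
                           raters = default_rater_panel(),
                           n_recordings = 40L, seed = 1L,
                           roles = attr(raters, "roles")) {
  if (is.null(roles)) {
    stop("rater roles must be supplied (automatic/manual/clinical)",
         call. = FALSE)
  }
  cohort <- simulate_cohort(model, raters, n_recordings, seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  recordings <- lapply(cohort, function(rec) {
    files <- lapply(names(rec$scorers), function(id) {
      fname <- sprintf("%s_%s.csv", rec$truth$recording_id, id)
      write_hypnogram(rec$scorers[[id]], file.path(dir, fname))
      fname
    })
    names(files) <- names(rec$scorers)
    list(id = rec$truth$recording_id,
         lights_off = rec$truth$lights_off,
         lights_on = rec$truth$lights_on,
         files = files)
  })
  manifest <- list(
    study_id = sprintf("synthetic-%d", seed),
    seed = seed,
    scorers = lapply(names(raters), function(id) {
      list(id = id, role = unname(roles[[id]]))
    }),
    recordings = recordings
  )
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}
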