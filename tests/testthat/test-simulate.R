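test_that("model validation catches non-stochastic matrices", {
  bad <- default_transition_matrix()
  bad[1, 1] <- 0.5
  expect_error(sleep_model(transition = bad), "sum to 1")
  expect_error(sleep_model(initial_probs = c(W = 1, N1 = 1, N2 = 0,
                                             N3 = 0, R = 0)), "sum to 1")
  badc <- symmetric_confusion(0.1)
  badc[2, 2] <- 0
  expect_error(rater_model(badc), "sum to 1")
})

test_that("a degenerate chain produces constant hypnograms", {
  mdl <- sleep_model(initial_probs = c(W = 0, N1 = 0, N2 = 1, N3 = 0,
                                       R = 0),
                     transition = diag(5),
                     epochs_range = c(30L, 30L))
  hyps <- simulate_truth(mdl, 3, seed = 1)
  for (h in hyps) expect_true(all(h$stages == "N2"))
  expect_identical(vapply(hyps, `[[`, character(1), "recording_id"),
                   c("rec01", "rec02", "rec03"))
})

test_that("cohort generation is deterministic under a fixed seed", {
  a <- simulate_cohort(n_recordings = 3, seed = 12)
  b <- simulate_cohort(n_recordings = 3, seed = 12)
  expect_identical(a, b)
  d <- simulate_cohort(n_recordings = 3, seed = 13)
  expect_false(identical(
    lapply(a, function(r) r$truth$stages),
    lapply(d, function(r) r$truth$stages)))
})

test_that("a uniform chain visits the stages uniformly", {
  mdl <- sleep_model(
    initial_probs = stats::setNames(rep(0.2, 5), sleep_stages()),
    transition = matrix(0.2, 5, 5,
                        dimnames = list(sleep_stages(), sleep_stages())),
    epochs_range = c(100000L, 100000L))
  h <- simulate_truth(mdl, 1, seed = 5)[[1]]
  freq <- table(factor(h$stages, levels = sleep_stages())) / length(h)
  expect_true(all(abs(freq - 0.2) < 0.01))
})

test_that("an error-free rater copies the truth exactly", {
  truth <- simulate_truth(sleep_model(epochs_range = c(50L, 60L)), 1,
                          seed = 3)[[1]]
  copy <- simulate_rater(truth, rater_model(symmetric_confusion(0)),
                         "copy", seed = 4)
  expect_identical(copy$stages, truth$stages)
  expect_identical(copy$recording_id, truth$recording_id)
  expect_identical(copy$scorer_id, "copy")
})

test_that("symmetric error eps gives rater-vs-truth OPA of 1 - eps", {
  truth <- simulate_truth(sleep_model(epochs_range = c(50000L, 50000L)),
                          1, seed = 7)[[1]]
  rated <- simulate_rater(truth, rater_model(symmetric_confusion(0.1)),
                          "r1", seed = 8)
  opa <- mean(rated$stages == truth$stages)
  expect_equal(opa, 0.9, tolerance = 0.005)
})

test_that("the generating confusion matrix is recovered from pooled counts", {
  eps <- 0.12
  truth <- simulate_truth(sleep_model(epochs_range = c(50000L, 50000L)),
                          1, seed = 9)[[1]]
  rated <- simulate_rater(truth, rater_model(symmetric_confusion(eps)),
                          "r1", seed = 10)
  m <- build_confusion(truth$stages, rated$stages)
  observed <- unclass(m) / rowSums(m)
  expect_true(all(abs(observed - symmetric_confusion(eps)) < 0.01))
})

test_that("U injection and end truncation follow the rater model", {
  truth <- simulate_truth(sleep_model(epochs_range = c(5000L, 5000L)),
                          1, seed = 11)[[1]]
  rated <- simulate_rater(truth,
                          rater_model(symmetric_confusion(0),
                                      u_prob = 0.1, truncation_max = 4L),
                          "r1", seed = 12)
  drop <- length(truth) - length(rated)
  expect_gte(drop, 0L); expect_lte(drop, 4L)
  u_rate <- mean(rated$stages == "U")
  expect_lt(abs(u_rate - 0.1), 0.02)
  kept <- rated$stages != "U"
  expect_true(all(rated$stages[kept] ==
                    truth$stages[seq_along(rated$stages)][kept]))
})

test_that("three-rater full consensus matches its closed form", {
  # three raters reporting independently with symmetric error eps agree
  # unanimously with probability (1-eps)^3 + 4 (eps/4)^3
  eps <- 0.092
  closed_form <- (1 - eps)^3 + 4 * (eps / 4)^3
  truths <- simulate_truth(sleep_model(epochs_range = c(3000L, 3000L)),
                           10, seed = 13)
  rm1 <- rater_model(symmetric_confusion(eps))
  full <- 0L; total <- 0L
  for (tr in truths) {
    mat <- vapply(1:3, function(i) {
      simulate_rater(tr, rm1, paste0("t", i))$stages
    }, character(length(tr)))
    full <- full + sum(mat[, 1] == mat[, 2] & mat[, 2] == mat[, 3])
    total <- total + nrow(mat)
  }
  expect_equal(full / total, closed_form, tolerance = 0.01)
  expect_equal(closed_form, 0.7487, tolerance = 5e-4)
})

test_that("simulate_study writes a loadable on-disk study", {
  dir <- tempfile("study")
  mf <- simulate_study(dir, n_recordings = 2, seed = 14,
                       model = sleep_model(epochs_range = c(40L, 60L)))
  expect_true(file.exists(mf))
  manifest <- read_study_manifest(mf)
  expect_identical(nrow(manifest$scorers), 5L)
  expect_identical(sort(manifest$scorers$role[manifest$scorers$role ==
                                                "manual"]),
                   rep("manual", 3))
  study <- load_study(manifest)
  expect_identical(length(study), 2L)
  expect_s3_class(study[["rec01"]][["machine"]], "hypnogram")
  # scorers share the recording's lights metadata
  expect_identical(study[["rec01"]][["machine"]]$lights_off,
                   study[["rec01"]][["tech2"]]$lights_off)
})
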