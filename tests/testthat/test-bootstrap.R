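pooled_opa_stat <- function(rs) {
  m <- do.call(rbind, rs)
  sum(m[, "agree"]) / sum(m[, "n"])
}

opa_rec <- function(agree, n) c(agree = agree, n = n)

test_that("bootstrap configuration is validated", {
  cfg <- bootstrap_config()
  expect_identical(cfg$n_resamples, 10000L)
  expect_equal(c(cfg$ci_lower_pct, cfg$ci_upper_pct), c(2.5, 97.5))
  expect_error(bootstrap_config(0))
  expect_error(bootstrap_config(ci_lower_pct = 97.5, ci_upper_pct = 2.5))
})

test_that("a single recording yields a degenerate zero-width interval", {
  recs <- list(opa_rec(73, 100))
  b <- cluster_bootstrap(recs, pooled_opa_stat,
                         bootstrap_config(500L, seed = 1))
  expect_equal(unname(b$point), 0.73)
  expect_equal(unname(b$lower), 0.73)
  expect_equal(unname(b$upper), 0.73)
})

test_that("the three-recording resample distribution has median 0.9", {
  # per-recording OPAs 0.8 / 0.9 / 1.0 on equal epoch counts: all 27
  # equally likely ordered draws are enumerable, so brute force replaces
  # Monte Carlo as the oracle
  vals <- c(0.8, 0.9, 1.0)
  draws <- expand.grid(a = vals, b = vals, c = vals)
  exact <- apply(draws, 1, mean)   # pooled OPA = mean at equal sizes
  expect_identical(length(exact), 27L)
  expect_equal(stats::median(exact), 0.9)

  recs <- lapply(vals, function(v) opa_rec(v * 100, 100))
  b <- cluster_bootstrap(recs, pooled_opa_stat,
                         bootstrap_config(4000L, seed = 9))
  expect_equal(unname(b$point), 0.9)
  expect_gte(b$lower, min(exact))
  expect_lte(b$upper, max(exact))
})

test_that("fixed seeds make bootstrap runs exactly reproducible", {
  set.seed(81)
  recs <- lapply(1:6, function(i) opa_rec(sample(50:90, 1), 100))
  b1 <- cluster_bootstrap(recs, pooled_opa_stat,
                          bootstrap_config(300L, seed = 7))
  b2 <- cluster_bootstrap(recs, pooled_opa_stat,
                          bootstrap_config(300L, seed = 7))
  expect_identical(b1, b2)
  b3 <- cluster_bootstrap(recs, pooled_opa_stat,
                          bootstrap_config(300L, seed = 8))
  expect_false(identical(b1$point, b3$point))
})

test_that("for a linear statistic the median approaches the plug-in", {
  recs <- as.list(as.numeric(1:6))
  mean_stat <- function(rs) mean(unlist(rs))
  b <- cluster_bootstrap(recs, mean_stat,
                         bootstrap_config(20000L, seed = 3))
  expect_equal(unname(b$point), 3.5, tolerance = 0.02)
  expect_equal(unname(b$plugin), 3.5)
})

test_that("undefined resamples are dropped per component and counted", {
  # statistic B is undefined whenever recording 1 is absent from the
  # resample
  recs <- list(1, 2, 3)
  stat <- function(rs) {
    has1 <- any(unlist(rs) == 1)
    c(a = mean(unlist(rs)), b = if (has1) 1 else NA_real_)
  }
  b <- cluster_bootstrap(recs, stat, bootstrap_config(400L, seed = 2))
  expect_identical(unname(b$n_defined[["a"]]), 400L)
  expect_lt(b$n_defined[["b"]], 400L)
  expect_equal(unname(b$point[["b"]]), 1)

  always_na <- function(rs) NA_real_
  expect_error(
    cluster_bootstrap(recs, always_na, bootstrap_config(50L, seed = 1)),
    "undefined in every")
})

test_that("paired differences of identical statistics are exactly zero", {
  recs <- lapply(1:5, function(i) opa_rec(60 + 5 * i, 100))
  b <- bootstrap_difference(recs, pooled_opa_stat, pooled_opa_stat,
                            bootstrap_config(200L, seed = 4))
  expect_equal(unname(b$point), 0)
  expect_equal(unname(b$lower), 0)
  expect_equal(unname(b$upper), 0)
  expect_identical(unname(b$significant), "none")
})

test_that("significance follows the CI-sign rule", {
  expect_identical(
    unname(hypnoagree:::ci_significance(c(0.1, -0.5, -0.2, NA),
                                        c(0.3, -0.1, 0.2, NA))),
    c("positive", "negative", "none", NA_character_))

  # an always-positive paired difference is flagged positive
  recs <- lapply(1:6, function(i) opa_rec(60 + 3 * i, 100))
  shifted <- function(rs) pooled_opa_stat(rs) + 0.05
  b <- bootstrap_difference(recs, shifted, pooled_opa_stat,
                            bootstrap_config(200L, seed = 5))
  expect_identical(unname(b$significant), "positive")
  expect_equal(unname(b$point), 0.05)
})

test_that("interval width shrinks as the number of recordings grows", {
  width_at <- function(n_rec, seed) {
    set.seed(seed)
    recs <- lapply(seq_len(n_rec), function(i) {
      opa_rec(rbinom(1, 100, 0.85), 100)
    })
    b <- cluster_bootstrap(recs, pooled_opa_stat,
                           bootstrap_config(500L, seed = seed))
    unname(b$upper - b$lower)
  }
  mean_width <- function(n_rec) {
    mean(vapply(1:10, function(s) width_at(n_rec, s), numeric(1)))
  }
  w5 <- mean_width(5); w20 <- mean_width(20); w80 <- mean_width(80)
  expect_gt(w5, w20)
  expect_gt(w20, w80)
})
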