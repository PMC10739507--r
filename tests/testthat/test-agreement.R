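cm <- function(cells, labels) {
  structure(matrix(cells, length(labels), length(labels), byrow = TRUE,
                   dimnames = list(reference = labels, test = labels)),
            class = c("confusion_matrix", "matrix"))
}

test_that("confusion matrices cross-tabulate epochs correctly", {
  m <- build_confusion(c("W", "W", "N1"), c("W", "N1", "N1"))
  expect_identical(m["W", "W"], 1L)
  expect_identical(m["W", "N1"], 1L)
  expect_identical(m["N1", "N1"], 1L)
  expect_identical(sum(m), 3L)

  s <- random_stages(30L)
  expect_identical(sum(diag(build_confusion(s, s))), 30L)

  expect_error(build_confusion(c("W"), c("W", "W")), "length")
  expect_error(build_confusion(c("U"), c("W")), "inadmissible")
  expect_error(build_confusion(character(0), character(0)), "zero epochs")
})

test_that("confusion counts agree with an independent per-cell tally", {
  set.seed(13)
  ref <- random_stages(1000L)
  test <- random_stages(1000L)
  m <- build_confusion(ref, test)
  expect_identical(sum(m), 1000L)
  for (i in sleep_stages()) {
    expect_identical(sum(m[i, ]), sum(ref == i))
    expect_identical(sum(m[, i]), sum(test == i))
    for (j in sleep_stages()) {
      expect_identical(m[i, j], sum(ref == i & test == j))
    }
  }
})

test_that("OPA and kappa reproduce hand-computed values", {
  two <- cm(c(2, 1, 1, 6), c("A", "B"))
  expect_equal(overall_percent_agreement(two), 0.8)
  # po = 0.8, pe = (3*3 + 7*7)/100 = 0.58 -> kappa = 0.22/0.42
  expect_equal(cohens_kappa(two), 0.22 / 0.42, tolerance = 1e-12)

  diag5 <- build_confusion(sleep_stages(), sleep_stages())
  expect_equal(overall_percent_agreement(diag5), 1)
  expect_equal(cohens_kappa(diag5), 1)

  # both scorers constant and identical: chance agreement is 1, kappa
  # undefined rather than zero
  const <- cm(c(10, 0, 0, 0), c("A", "B"))
  expect_true(is.na(cohens_kappa(const)))
  expect_equal(overall_percent_agreement(const), 1)
})

test_that("kappa matches the independent e1071 implementation", {
  skip_if_not_installed("e1071")
  set.seed(31)
  for (i in 1:100) {
    m <- random_confusion_counts(sample(50:400, 1))
    expect_equal(cohens_kappa(m),
                 e1071::classAgreement(unclass(m))$kappa,
                 tolerance = 1e-10)
  }
})

test_that("per-stage PPA/NPA/PPV follow their count definitions", {
  # TP = 3, ref_s = 4, test_s = 5, N = 10
  m <- cm(c(3, 1, 2, 4), c("s", "other"))
  st <- per_stage_stats(m, "s")
  expect_equal(st$ppa, 0.75)
  expect_equal(st$ppv, 0.6)
  expect_equal(st$npa, (10 - 4 - 5 + 3) / 6)

  perfect <- cm(c(4, 0, 0, 6), c("A", "B"))
  for (s in c("A", "B")) {
    expect_equal(unlist(per_stage_stats(perfect, s)),
                 c(ppa = 1, npa = 1, ppv = 1))
  }

  # absent stage: zero denominators propagate as NA, not 0
  none <- build_confusion(c("W", "N2"), c("W", "N2"))
  st0 <- per_stage_stats(none, "R")
  expect_true(is.na(st0$ppa) && is.na(st0$ppv))
  expect_equal(st0$npa, 1)
})

test_that("agreement_vector is consistent with the per-statistic API", {
  set.seed(17)
  for (i in 1:25) {
    m <- random_confusion_counts(120L)
    v <- hypnoagree:::agreement_vector(m)
    expect_equal(v[["opa"]], overall_percent_agreement(m))
    expect_equal(v[["kappa"]], cohens_kappa(m))
    for (s in sleep_stages()) {
      st <- per_stage_stats(m, s)
      expect_equal(v[[paste0("ppa_", s)]], st$ppa)
      expect_equal(v[[paste0("npa_", s)]], st$npa)
      expect_equal(v[[paste0("ppv_", s)]], st$ppv)
    }
  }
})

test_that("OPA/kappa are transpose-symmetric and PPA/PPV are dual", {
  set.seed(19)
  for (i in 1:200) {
    m <- random_confusion_counts(sample(20:200, 1))
    tm <- structure(t(unclass(m)), class = class(m))
    expect_equal(overall_percent_agreement(m),
                 overall_percent_agreement(tm))
    expect_equal(cohens_kappa(m), cohens_kappa(tm))
    for (s in sleep_stages()) {
      a <- per_stage_stats(m, s)
      b <- per_stage_stats(tm, s)
      expect_equal(a$ppa, b$ppv)
      expect_equal(a$ppv, b$ppa)
    }
  }
})

test_that("pooled confusion equals the sum of per-recording matrices", {
  set.seed(23)
  seqs <- lapply(1:4, function(i) {
    list(ref = random_stages(50L), test = random_stages(50L))
  })
  per_rec <- lapply(seqs, function(s) build_confusion(s$ref, s$test))
  pooled <- pool_confusion(per_rec)
  concat <- build_confusion(unlist(lapply(seqs, `[[`, "ref")),
                            unlist(lapply(seqs, `[[`, "test")))
  expect_identical(unclass(pooled), unclass(concat))
})

test_that("marginal identities hold on random matrices", {
  set.seed(29)
  for (i in 1:50) {
    m <- random_confusion_counts(100L)
    expect_identical(sum(rowSums(m)), sum(colSums(m)))
    for (s in sleep_stages()) {
      expect_lte(m[s, s], min(sum(m[s, ]), sum(m[, s])))
    }
    expect_lte(cohens_kappa(m), 1 + 1e-12)
  }
})

panel_from <- function(cols) {
  align_and_filter(lapply(names(cols), function(id) {
    hyp(cols[[id]], scorer = id)
  }))
}

test_that("identical raters give unit panel averages", {
  s <- random_stages(40L)
  set <- panel_from(list(t1 = s, t2 = s, t3 = s, machine = s))
  res <- directional_panel_averages(set, machine = "machine")
  for (block in list(res$within, res$machine)) {
    defined <- !is.na(block$mean)
    expect_true(all(abs(block$mean[defined] - 1) < 1e-12))
    expect_equal(block$mean[["opa"]], 1)
    expect_equal(block$mean[["kappa"]], 1)
  }
  expect_identical(res$within$n_pairs, 6L)  # 3 manual raters -> 6 ordered
})

test_that("within-panel average PPA equals average PPV for every stage", {
  set.seed(37)
  set <- panel_from(list(t1 = random_stages(120L),
                         t2 = random_stages(120L),
                         t3 = random_stages(120L)))
  res <- directional_panel_averages(set)
  expect_identical(res$within$n_pairs, 6L)
  for (s in sleep_stages()) {
    expect_equal(res$within$mean[[paste0("ppa_", s)]],
                 res$within$mean[[paste0("ppv_", s)]])
  }
})

test_that("within-panel OPA averages the pairwise OPAs", {
  # constructed so the three pairwise OPAs are 0.75, 0.5 and 0.25
  set <- panel_from(list(A = c("W", "W", "W", "N2"),
                         B = c("W", "W", "W", "N3"),
                         C = c("W", "N1", "N1", "N2")))
  pair_opa <- function(x, y) mean(x == y)
  expect_equal(pair_opa(set$stages[, 1], set$stages[, 2]), 0.75)
  expect_equal(pair_opa(set$stages[, 1], set$stages[, 3]), 0.5)
  expect_equal(pair_opa(set$stages[, 2], set$stages[, 3]), 0.25)
  res <- directional_panel_averages(set)
  expect_equal(res$within$mean[["opa"]], 0.5)
})

test_that("machine-vs-panel averages use the machine as test scorer", {
  set.seed(41)
  cols <- list(t1 = random_stages(80L), t2 = random_stages(80L),
               t3 = random_stages(80L), m = random_stages(80L))
  set <- panel_from(cols)
  res <- directional_panel_averages(set, machine = "m")
  expect_identical(res$machine$n_pairs, 3L)
  manual_mean <- rowMeans(vapply(c("t1", "t2", "t3"), function(r) {
    hypnoagree:::agreement_vector(build_confusion(cols[[r]], cols$m))
  }, numeric(17)), na.rm = TRUE)
  expect_equal(res$machine$mean[["opa"]], manual_mean[["opa"]])
  expect_equal(res$machine$mean[["ppa_W"]], manual_mean[["ppa_W"]])
  expect_error(directional_panel_averages(set, machine = "zz"),
               "not in panel")
})
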