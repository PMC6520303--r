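test_that("matrix correlation is affine-invariant and matches the textbook formula", {
  set.seed(1)
  W1 <- random_weight_matrix(8)
  W2 <- random_weight_matrix(8)
  m1 <- make_cm(W1); m2 <- make_cm(W2)
  expect_equal(matrix_correlation(m1, m1), 1)
  W1b <- pmin(0.3 * W1 + 0.1, 1); diag(W1b) <- 0
  m1b <- make_cm(W1b)
  expect_equal(matrix_correlation(m1, m1b), 1)
  v1 <- W1[upper.tri(W1)]; v2 <- W2[upper.tri(W2)]
  r_direct <- sum((v1 - mean(v1)) * (v2 - mean(v2))) /
    sqrt(sum((v1 - mean(v1))^2) * sum((v2 - mean(v2))^2))
  expect_equal(matrix_correlation(m1, m2), r_direct)
  flat <- make_cm(matrix(0.5, 8, 8) - diag(0.5, 8))
  expect_error(matrix_correlation(m1, flat), "zero variance")
})

test_that("global connectivity is the upper-triangle mean", {
  expect_equal(global_connectivity(matrix(0.5, 9, 9) - diag(0.5, 9)), 0.5)
  M <- matrix(0, 3, 3)
  M[upper.tri(M)] <- c(0.2, 0.4, 0.6)
  M <- M + t(M)
  expect_equal(global_connectivity(M), 0.4)
})

test_that("ICC handles degenerate and shifted tables as the model dictates", {
  tab <- cbind(c(1, 2, 3), c(1, 2, 3))
  expect_warning(v <- icc(tab), "identically")
  expect_equal(v, 1)
  # consistency ICC ignores an additive session effect
  expect_warning(v2 <- icc(cbind(c(1, 2, 3), c(1, 2, 3) + 5)))
  expect_equal(v2, 1)
  expect_error(icc(matrix(2, 4, 2)), "undefined")
  expect_error(icc(cbind(1:2, 1:2)), "3 subjects")
})

test_that("ICC matches the two-way ANOVA oracle on random tables", {
  set.seed(14)
  for (i in 1:20) {
    n <- sample(5:12, 1); k <- sample(2:4, 1)
    tab <- matrix(rnorm(n * k), n, k)
    expect_equal(icc(tab), oracle_icc_twoway(tab), tolerance = 1e-10)
    expect_equal(icc(tab, model = "oneway"), oracle_icc_oneway(tab),
                 tolerance = 1e-10)
  }
})

test_that("ICC is invariant to affine rescaling and per-session constants", {
  set.seed(5)
  tab <- matrix(rnorm(20), 10, 2)
  expect_equal(icc(3 * tab + 7), icc(tab))
  shifted <- tab + matrix(c(0, 2), 10, 2, byrow = TRUE)
  expect_equal(icc(shifted), icc(tab))
})

test_that("COV is sd over mean", {
  expect_equal(cov_subjects(rep(4, 10)), 0)
  expect_equal(cov_subjects(c(1, 3)), sqrt(2) / 2)
  set.seed(8)
  v <- rlnorm(30)
  expect_equal(cov_subjects(v), sd(v) / mean(v))
  expect_error(cov_subjects(c(-1, 1)), "zero mean")
})

test_that("bootstrap CI is seeded, degenerate-safe, and error-guarded", {
  tab <- matrix(rep(c(1, 2, 3), 2), 3, 2)
  ci <- bootstrap_ci(function(d) mean(d), tab, n_boot = 50, seed = 1)
  ci2 <- bootstrap_ci(function(d) mean(d), tab, n_boot = 50, seed = 1)
  expect_identical(ci, ci2)
  cst <- bootstrap_ci(function(d) 42, tab, n_boot = 20, seed = 2)
  expect_equal(unname(cst), c(42, 42))
  expect_error(
    bootstrap_ci(function(d) stop("no"), tab, n_boot = 20, seed = 3),
    "undefined on")
})

test_that("unit-wise ICC: stable edges score 1 and match the per-edge oracle", {
  co <- make_matrix_cohort(8, 5, noise = 0, seed = 3)   # session2 == session1
  uw <- suppressWarnings(icc_unitwise(co$s1, co$s2))
  expect_true(all(abs(uw$per_edge$icc - 1) < 1e-12))
  expect_equal(uw$median, 1)
  expect_equal(uw$n_edges, 10)
  # noisy cohort against the ANOVA oracle, edge by edge
  co2 <- make_matrix_cohort(10, 4, noise = 0.05, seed = 9)
  uw2 <- icc_unitwise(co2$s1, co2$s2)
  v1 <- sapply(co2$s1, function(m) m$values[upper.tri(m$values)])
  v2 <- sapply(co2$s2, function(m) m$values[upper.tri(m$values)])
  for (e in seq_len(nrow(uw2$per_edge)))
    expect_equal(uw2$per_edge$icc[e], oracle_icc_twoway(cbind(v1[e, ], v2[e, ])),
                 tolerance = 1e-9)
})

test_that("half-rerandomized edges pull the median between the subpopulations", {
  nE <- 6 * 5 / 2
  stable <- rep(c(TRUE, FALSE), length.out = nE)
  co <- make_matrix_cohort(25, 6, stable_mask = stable, noise = 0.02, seed = 7)
  uw <- icc_unitwise(co$s1, co$s2)
  med_stable <- median(uw$per_edge$icc[stable])
  med_unstable <- median(uw$per_edge$icc[!stable])
  expect_gt(med_stable, med_unstable)
  expect_gte(uw$median, med_unstable)
  expect_lte(uw$median, med_stable)
})

test_that("top-percentile selection sizes and tie handling", {
  # 32-channel cohort: 496 edges, top 25% = 124
  co <- make_matrix_cohort(3, 32, noise = 0.01, seed = 2)
  mask <- top_percentile_edges(co$s1, co$s2, 25)
  expect_equal(sum(mask[upper.tri(mask)]), 124)
  expect_true(isSymmetric(mask))
  # all-equal strengths: everything ties at the cutoff
  flat <- lapply(1:3, function(s) make_cm(matrix(0.5, 4, 4) - diag(0.5, 4),
                                          sprintf("S%02d", s)))
  expect_warning(m2 <- top_percentile_edges(flat, flat, 25), "ties")
  expect_true(all(m2[upper.tri(m2)]))
  expect_error(top_percentile_edges(co$s1, co$s2, 0), "percentile")
})

test_that("reliability classification follows the conventional bins", {
  expect_identical(classify_reliability(c(-0.3, 0.39, 0.45, 0.7, 0.9)),
                   c("low", "low", "mediocre", "good", "excellent"))
})
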