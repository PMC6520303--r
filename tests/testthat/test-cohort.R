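test_that("cohort spec validation rejects invalid parameters", {
  expect_error(cohort_spec(n_subjects = 2, n_channels = 4, duration = 10,
                           bands = alpha_band(), session_stability = 1.5),
               "session_stability")
  expect_error(cohort_spec(n_subjects = 2, n_channels = 4, duration = 10,
                           bands = alpha_band(), phase_lag = pi),
               "multiple of pi")
  G <- matrix(runif(16), 4, 4)   # not symmetric
  expect_error(cohort_spec(n_subjects = 2, n_channels = 4, duration = 10,
                           bands = alpha_band(), coupling_base = G),
               "symmetric")
  G2 <- default_coupling(4); diag(G2) <- 0.2
  expect_error(cohort_spec(n_subjects = 2, n_channels = 4, duration = 10,
                           bands = alpha_band(), coupling_base = G2),
               "diagonal")
})

test_that("identical spec and seed give bit-identical cohorts", {
  spec <- cohort_spec(n_subjects = 2, n_channels = 4, sampling_rate = 128,
                      duration = 8, bands = alpha_band(), seed = 33)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1, c2)
})

test_that("per-subject substreams survive a change of n_subjects", {
  mk <- function(n) generate_cohort(
    cohort_spec(n_subjects = n, n_channels = 4, sampling_rate = 128,
                duration = 8, bands = alpha_band(), seed = 9))
  small <- mk(2); big <- mk(4)
  expect_identical(small[["S01_1"]]$data, big[["S01_1"]]$data)
  expect_identical(small[["S02_2"]]$data, big[["S02_2"]]$data)
})

test_that("ground-truth coupling deviations correlate at session_stability", {
  for (rho in c(0.3, 0.9)) {
    spec <- cohort_spec(n_subjects = 15, n_channels = 12, sampling_rate = 64,
                        duration = 2, bands = alpha_band(),
                        coupling_base = matrix(0.5, 12, 12) - diag(0.5, 12),
                        subject_sd = 0.1, session_stability = rho, seed = 4)
    co <- generate_cohort(spec)
    tr <- attr(co, "couplings")
    ut <- upper.tri(matrix(0, 12, 12))
    d1 <- unlist(lapply(tr, function(s) s$session1$alpha[ut] - 0.5))
    d2 <- unlist(lapply(tr, function(s) s$session2$alpha[ut] - 0.5))
    expect_lt(abs(cor(d1, d2) - rho), 0.12)
  }
})

test_that("a single strongly coupled edge yields PLI near 1 there and small elsewhere", {
  G <- matrix(0, 6, 6); G[1, 2] <- G[2, 1] <- 0.9
  spec <- cohort_spec(n_subjects = 1, n_channels = 6, sampling_rate = 256,
                      duration = 60, bands = alpha_band(), coupling_base = G,
                      subject_sd = 0, session_stability = 1, noise_sd = 0,
                      phase_lag = pi / 2, seed = 7)
  co <- generate_cohort(spec)
  ep <- epoch_and_select(co[["S01_1"]], 5, 10, band_name = "alpha")
  P <- connectivity_matrix(ep, "pli")$values
  expect_gt(P[1, 2], 0.95)
  others <- P[upper.tri(P)]
  others <- others[-1]
  expect_lt(max(others), 0.35)   # finite-sample null bias only
})

test_that("zero coupling with noise leaves all PLI at the finite-sample null level", {
  spec <- cohort_spec(n_subjects = 1, n_channels = 6, sampling_rate = 256,
                      duration = 60,
                      bands = data.frame(name = "wide", low = 6, high = 30),
                      coupling_base = matrix(0, 6, 6),
                      subject_sd = 0, session_stability = 1, noise_sd = 1,
                      seed = 3)
  co <- generate_cohort(spec)
  ep <- epoch_and_select(co[["S01_1"]], 5, 10, band_name = "wide")
  P <- connectivity_matrix(ep, "pli")$values
  expect_lt(mean(P[upper.tri(P)]), 0.15)
  expect_lt(max(P[upper.tri(P)]), 0.3)
})

test_that("perfect stability without noise reproduces session matrices up to epoch sampling", {
  spec <- cohort_spec(n_subjects = 1, n_channels = 6, sampling_rate = 256,
                      duration = 60, bands = alpha_band(),
                      subject_sd = 0.15, session_stability = 1, noise_sd = 0,
                      seed = 12)
  co <- generate_cohort(spec)
  cm <- lapply(1:2, function(k) {
    ep <- epoch_and_select(co[[sprintf("S01_%d", k)]], 5, 10,
                           band_name = "alpha")
    connectivity_matrix(ep, "pli")
  })
  expect_gt(matrix_correlation(cm[[1]], cm[[2]]), 0.9)
})

test_that("estimated PLI is nondecreasing in the generated coupling weight", {
  plis <- sapply(c(0.2, 0.5, 0.8), function(g) {
    G <- matrix(0, 4, 4); G[1, 2] <- G[2, 1] <- g
    spec <- cohort_spec(n_subjects = 1, n_channels = 4, sampling_rate = 256,
                        duration = 40, bands = alpha_band(),
                        coupling_base = G, subject_sd = 0,
                        session_stability = 1, noise_sd = 0.5, seed = 21)
    co <- generate_cohort(spec)
    ep <- epoch_and_select(co[["S01_1"]], 5, 8, band_name = "alpha")
    connectivity_matrix(ep, "pli")$values[1, 2]
  })
  expect_true(all(diff(plis) > 0))
})

test_that("inject_artifacts with zero rates is the identity", {
  spec <- cohort_spec(n_subjects = 1, n_channels = 4, sampling_rate = 128,
                      duration = 10, bands = alpha_band(), seed = 2)
  rec <- generate_cohort(spec)[["S01_1"]]
  out <- inject_artifacts(rec, bad_channel_fraction = 0, jump_rate = 0)
  expect_identical(out$recording$data, rec$data)
  expect_identical(out$truth$bad_channels, character(0))
})

test_that("an injected jump is located by the first-difference oracle", {
  spec <- cohort_spec(n_subjects = 1, n_channels = 4, sampling_rate = 128,
                      duration = 20, bands = alpha_band(), seed = 6)
  rec <- generate_cohort(spec)[["S01_1"]]
  out <- inject_artifacts(rec, jump_rate = 1, seed = 44, jump_sd = 50)
  expect_gt(nrow(out$truth$jumps), 0)
  # a channel carrying exactly one jump: the derivative argmax finds it
  counts <- table(out$truth$jumps$channel)
  ch <- names(counts)[counts == 1][1]
  expect_false(is.na(ch))
  j <- out$truth$jumps[out$truth$jumps$channel == ch, ]
  ci <- match(ch, rec$channel_labels)
  expect_equal(which.max(abs(diff(out$recording$data[ci, ]))) + 1L, j$sample)
})

test_that("an injected bad channel is recovered by downstream detection", {
  spec <- cohort_spec(n_subjects = 1, n_channels = 8, sampling_rate = 128,
                      duration = 100, bands = alpha_band(), seed = 8)
  rec <- generate_cohort(spec)[["S01_1"]]
  out <- inject_artifacts(rec, bad_channel_fraction = 1 / 8, seed = 15)
  expect_length(out$truth$bad_channels, 1L)
  mask <- detect_artifacts(out$recording)
  expect_identical(detect_bad_channels(out$recording, mask),
                   out$truth$bad_channels)
})
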