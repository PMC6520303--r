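make_tone_rec <- function(freqs, fs, dur, amp = 1) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  dat <- t(sapply(freqs, function(f) amp * sin(2 * pi * f * t)))
  eeg_recording(matrix(dat, nrow = length(freqs)), fs,
                subject_id = "T", session_id = 1L)
}

fft_amplitude <- function(x, fs, f) {
  n <- length(x)
  sp <- abs(stats::fft(x)) / n * 2
  freqs <- (seq_len(n) - 1) * fs / n
  sp[which.min(abs(freqs - f))]
}

test_that("resampling produces the expected length and preserves tones", {
  rec <- make_tone_rec(5, 2048, 10)
  out <- resample_recording(rec, 512)
  expect_equal(n_samples(out), 5120)    # 10 s x 512 Hz
  expect_equal(out$sampling_rate, 512)
  # spectral peak at 5 Hz preserved within 1%
  a <- fft_amplitude(out$data[1, ], 512, 5)
  expect_lt(abs(a - 1), 0.01)
  # identity at equal rates
  expect_identical(resample_recording(rec, 2048)$data, rec$data)
  expect_error(resample_recording(rec, 4096), "exceeds")
})

test_that("broadband filter preserves the passband and rejects outside it", {
  rec <- make_tone_rec(c(50, 100), 512, 30)
  out <- broadband_filter(rec, 0.1, 70)
  mid <- 3000:12000
  expect_lt(abs(max(abs(out$data[1, mid])) - 1), 0.02)       # 50 Hz kept
  expect_lt(max(abs(out$data[2, mid])), 0.1)                 # 100 Hz gone
  # DC offset removed by the 0.1 Hz high-pass (judge the settled middle,
  # away from the ~10 s transient of the 0.1 Hz edge)
  dc <- eeg_recording(matrix(10, 1, 512 * 30), 512)
  filtered <- broadband_filter(dc, 0.1, 70)$data[1, ]
  expect_lt(abs(mean(filtered[5121:10240])), 0.1)
})

test_that("band filtering is idempotent in passband energy", {
  rec <- make_tone_rec(10, 256, 20)
  once <- eegnetrel:::zp_bandpass(rec$data[1, ], 256, 2, 40)
  twice <- eegnetrel:::zp_bandpass(once, 256, 2, 40)
  mid <- 1000:4000
  p1 <- mean(once[mid]^2); p2 <- mean(twice[mid]^2)
  expect_lt(abs(p2 - p1) / p1, 0.01)
})

test_that("band decomposition routes a tone to its band", {
  out <- band_decompose(make_tone_rec(4.5, 512, 20))
  expect_named(out, c("delta", "theta", "alpha1", "alpha2", "beta", "gamma"))
  mid <- 2000:8000
  pow <- sapply(out, function(r) mean(r$data[1, mid]^2))
  expect_gt(pow[["theta"]] / max(pow[names(pow) != "theta"]), 10)
  # empty band list gives empty output
  expect_length(band_decompose(make_tone_rec(4.5, 512, 2),
                               eeg_bands()[0, ]), 0)
  bad <- data.frame(name = "hf", low = 100, high = 300)
  expect_error(band_decompose(make_tone_rec(4.5, 512, 2), bad), "hf")
})

test_that("artifact detection flags injected steps but not clean data", {
  set.seed(10)
  fs <- 128
  dat <- matrix(rnorm(4 * fs * 60), 4, fs * 60)
  dat <- eegnetrel:::zp_bandpass(dat, fs, 1, 30)
  rec <- eeg_recording(dat, fs)
  clean_mask <- detect_artifacts(rec)
  expect_lt(mean(clean_mask), 0.01)
  # a 50-sd step on channel 2
  step_at <- 3000
  dat2 <- dat
  dat2[2, step_at:ncol(dat2)] <- dat2[2, step_at:ncol(dat2)] + 50 * sd(dat[2, ])
  mask <- detect_artifacts(eeg_recording(dat2, fs))
  expect_true(mask[2, step_at])
  # constant channel is fully flagged
  dat3 <- dat; dat3[3, ] <- 0
  expect_true(all(detect_artifacts(eeg_recording(dat3, fs))[3, ]))
})

test_that("bad-channel rule is strictly greater than half", {
  rec <- eeg_recording(matrix(rnorm(300), 3, 100), 100,
                       channel_labels = c("A", "B", "C"))
  mask <- matrix(FALSE, 3, 100)
  mask[1, 1:60] <- TRUE   # 60%
  mask[2, 1:50] <- TRUE   # exactly 50%
  expect_identical(detect_bad_channels(rec, mask), "A")
  expect_identical(detect_bad_channels(rec, matrix(FALSE, 3, 100)),
                   character(0))
  expect_error(detect_bad_channels(rec, matrix(FALSE, 3, 99)), "shape")
})

test_that("channel harmonization removes the union from both sessions", {
  labs <- sprintf("E%02d", 1:32)
  set.seed(6)
  r1 <- eeg_recording(matrix(rnorm(32 * 100), 32, 100), 100, labs, "S1", 1L)
  r2 <- eeg_recording(matrix(rnorm(32 * 100), 32, 100), 100, labs, "S1", 2L)
  out <- harmonize_channels(r1, r2, bad1 = "E01", bad2 = "E32")
  expect_identical(out$session1$channel_labels, labs[2:31])
  expect_identical(out$session2$channel_labels, labs[2:31])
  expect_equal(30 * 29 / 2, 435)   # retained-pair arithmetic
  # symmetric in its session arguments
  swapped <- harmonize_channels(r2, r1, bad1 = "E32", bad2 = "E01")
  expect_identical(swapped$session2$data, out$session1$data)
  # identity with no bad channels
  id <- harmonize_channels(r1, r2)
  expect_identical(id$session1$data, r1$data)
  expect_error(harmonize_channels(r1, r2, bad1 = labs[1:31]),
               "fewer than 2")
})

test_that("epoching selects seeded clean epochs of the printed length", {
  fs <- 512
  rec <- eeg_recording(matrix(rnorm(2 * fs * 120), 2, fs * 120), fs)
  ep <- epoch_and_select(rec, 5, 20, seed = 3)
  expect_equal(dim(ep$epochs), c(20, 2, 2560))     # 5 s x 512 Hz = 2,560
  ep2 <- epoch_and_select(rec, 5, 20, seed = 3)
  expect_identical(ep$epochs, ep2$epochs)          # determinism
  # all candidates selected preserves order and reconstructs the record
  all_ep <- epoch_and_select(rec, 5, 24, seed = 1)
  recon <- do.call(cbind, lapply(1:24, function(i)
    matrix(all_ep$epochs[i, , ], nrow = 2)))
  expect_equal(recon, unname(rec$data[, 1:(24 * 2560)]))
  # artifact-contaminated epochs leave the candidate pool
  mask <- matrix(FALSE, 2, fs * 120)
  mask[1, 1:(5 * fs * 10)] <- TRUE                 # kills first 10 epochs
  ep3 <- epoch_and_select(rec, 5, 14, seed = 2, artifact_mask = mask)
  expect_equal(dim(ep3$epochs)[1], 14)
  expect_false(any(vapply(1:14, function(i)
    any(abs(ep3$epochs[i, , ] - rec$data[, 1:2560]) < 1e-12), logical(1))))
  expect_error(epoch_and_select(rec, 5, 20, artifact_mask = mask),
               "14 clean epochs")
})
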