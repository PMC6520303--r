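# Preprocessing: resampling, zero-phase filtering, artifact and bad-channel
# handling, band decomposition, epoching.

# Zero-phase band-pass as a cascade of Butterworth high-pass then low-pass,
# each applied forward-backward (signal::filtfilt). The cascade is used
# instead of a single band-pass section because very asymmetric edges
# (e.g. 0.1 and 70 Hz at fs 512) put poles too close to the unit circle
# for a stable 2n-pole band-pass design.
zp_bandpass <- function(x, fs, low, high, order_hp = 3L, order_lp = 3L) {
  nyq <- fs / 2
  if (!(low > 0 && high > low && high < nyq))
    stop(sprintf("invalid band edges [%g, %g] Hz at fs %g Hz", low, high, fs))
  hp <- signal::butter(order_hp, low / nyq, type = "high")
  lp <- signal::butter(order_lp, high / nyq, type = "low")
  filt1 <- function(v) signal::filtfilt(lp, signal::filtfilt(hp, v))
  if (is.matrix(x)) t(apply(x, 1L, filt1)) else filt1(x)
}

#' Resample a recording to a lower rate
#'
#' Anti-aliased downsampling of every channel: a zero-phase Butterworth
#' low-pass at 80% of the target Nyquist removes content that would alias,
#' then the filtered signal is decimated (integer rate ratios, e.g.
#' 2048 to 512 Hz) or interpolated by cubic spline onto the new time grid.
#' The output has \code{floor(n * target_rate / sampling_rate)} samples
#' and amplitudes are preserved throughout the retained band.
#'
#' @param rec An \code{eeg_recording}.
#' @param target_rate Target sampling rate in Hz; must not exceed the
#'   original rate.
#' @return The resampled \code{eeg_recording}.
#' @export
resample_recording <- function(rec, target_rate) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.numeric(target_rate) || target_rate <= 0)
    stop("`target_rate` must be positive")
  if (target_rate > rec$sampling_rate)
    stop("`target_rate` exceeds the original sampling rate")
  if (target_rate == rec$sampling_rate) return(rec)
  fs <- rec$sampling_rate
  n_in <- ncol(rec$data)
  n_out <- floor(n_in * target_rate / fs)
  lp <- signal::butter(8, 0.8 * target_rate / fs, type = "low")
  q <- fs / target_rate
  int_ratio <- abs(q - round(q)) < 1e-9
  t_new <- (seq_len(n_out) - 1) / target_rate
  t_old <- (seq_len(n_in) - 1) / fs
  out <- t(apply(rec$data, 1L, function(v) {
    f <- signal::filtfilt(lp, v)
    if (int_ratio) f[seq(1L, by = round(q), length.out = n_out)]
    else stats::spline(t_old, f, xout = t_new)$y
  }))
  eeg_recording(out, target_rate, rec$channel_labels,
                rec$subject_id, rec$session_id)
}

#' Broadband band-pass filter
#'
#' Zero-phase (forward-backward) Butterworth band-pass, default 0.1-70 Hz.
#' Implemented as a high-pass / low-pass cascade; the low-pass order is
#' higher by default so that tones well inside the passband (e.g. 50 Hz
#' under a 70 Hz edge) are preserved within ~1-2% while one octave outside
#' the passband is attenuated by more than 20 dB.
#'
#' @param rec An \code{eeg_recording}.
#' @param low,high Band edges in Hz; \code{0 < low < high < } Nyquist.
#' @param order_hp Butterworth order of the high-pass section (per pass).
#' @param order_lp Butterworth order of the low-pass section (per pass).
#' @return The filtered \code{eeg_recording}.
#' @export
broadband_filter <- function(rec, low = 0.1, high = 70,
                             order_hp = 3L, order_lp = 6L) {
  stopifnot(inherits(rec, "eeg_recording"))
  out <- zp_bandpass(rec$data, rec$sampling_rate, low, high,
                     order_hp = order_hp, order_lp = order_lp)
  eeg_recording(out, rec$sampling_rate, rec$channel_labels,
                rec$subject_id, rec$session_id)
}

#' Decompose a recording into frequency bands
#'
#' One zero-phase Butterworth band-passed copy of the recording per band,
#' applied to the continuous record (before epoching) to keep filter
#' transients away from epoch edges.
#'
#' @param rec An \code{eeg_recording}.
#' @param bands A data.frame with columns \code{name}, \code{low},
#'   \code{high} (Hz), e.g. \code{\link{eeg_bands}()}.
#' @param order Butterworth order per pass for both edges.
#' @return A named list of band-filtered \code{eeg_recording}s.
#' @export
band_decompose <- function(rec, bands = eeg_bands(), order = 3L) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(bands) == 0L) return(setNames(list(), character(0)))
  nyq <- rec$sampling_rate / 2
  bad <- bands$low <= 0 | bands$high <= bands$low | bands$high >= nyq
  if (any(bad))
    stop("invalid band edges for: ", paste(bands$name[bad], collapse = ", "))
  out <- lapply(seq_len(nrow(bands)), function(i) {
    filtered <- zp_bandpass(rec$data, rec$sampling_rate,
                            bands$low[i], bands$high[i],
                            order_hp = order, order_lp = order)
    eeg_recording(filtered, rec$sampling_rate, rec$channel_labels,
                  rec$subject_id, rec$session_id)
  })
  setNames(out, bands$name)
}

#' Flag artifact samples
#'
#' Flags (a) jump/cut discontinuities: samples whose absolute first
#' difference exceeds \code{jump_z} robust-z units, where each channel's
#' scale is estimated from the lower quartile of its |first difference|
#' (the lower quartile reflects the clean portion of a channel even when
#' more than half of it is artifactual, so a mostly-bad channel cannot
#' mask its own discontinuities); and (b)
#' high-variance windows: fixed-length windows whose log variance exceeds
#' \code{var_z} robust-z units relative to the channel's own windows
#' (log variance because window variances are right-skewed, and a
#' per-channel reference because channels legitimately differ in scale).
#' The variance reference is estimated from the lower quantiles (10th and
#' 25th percentiles) of the channel's log window variances, which remain
#' in the clean portion even when most of a channel is artifactual, so a
#' mostly-bad channel cannot mask itself. A constant (flat) channel is
#' degenerate and is flagged entirely.
#'
#' @param rec An \code{eeg_recording}.
#' @param jump_z Robust-z threshold on |first difference| (default 8).
#' @param var_z Robust-z threshold on window variance (default 4).
#' @param window_s Window length in seconds for the variance rule.
#' @return Logical channels x samples matrix; \code{TRUE} = artifact.
#' @export
detect_artifacts <- function(rec, jump_z = 8, var_z = 4, window_s = 5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (jump_z <= 0 || var_z <= 0) stop("thresholds must be positive")
  x <- rec$data
  n_ch <- nrow(x); n_s <- ncol(x)
  mask <- matrix(FALSE, n_ch, n_s, dimnames = list(rec$channel_labels, NULL))

  flat <- apply(x, 1L, function(v) diff(range(v)) == 0)
  mask[flat, ] <- TRUE

  live <- which(!flat)
  if (length(live) == 0L) return(mask)

  # jumps: per-channel robust scale from the lower quartile of |diff|
  # (0.3186 = 25th percentile of a half-normal, for Gaussian consistency)
  d <- abs(t(diff(t(x[live, , drop = FALSE]))))
  for (r in seq_along(live)) {
    sigma <- stats::quantile(d[r, ], 0.25, names = FALSE) / 0.3186
    if (sigma == 0) sigma <- stats::median(d[r, ]) / 0.6745
    k <- if (sigma > 0) which(d[r, ] > jump_z * sigma) else which(d[r, ] > 0)
    # a discontinuity between samples k and k+1 taints both
    if (length(k)) mask[live[r], unique(c(k, k + 1L))] <- TRUE
  }

  # high-variance windows: per-channel robust z of log window variance
  w <- max(1L, round(window_s * rec$sampling_rate))
  n_win <- n_s %/% w
  if (n_win >= 2L) {
    v <- sapply(seq_len(n_win), function(j) {
      idx <- ((j - 1L) * w + 1L):(j * w)
      apply(x[live, idx, drop = FALSE], 1L, stats::var)
    })
    v <- log(matrix(v, nrow = length(live)))
    for (r in seq_along(live)) {
      ok <- is.finite(v[r, ])       # zero-variance windows: flat cuts
      q <- stats::quantile(v[r, ok], c(0.10, 0.25), names = FALSE)
      # Gaussian-consistent scale from the q10-q25 distance (0.6071 =
      # qnorm(0.25) - qnorm(0.10)); the implied clean median sits
      # 0.6745 scale units above q25
      s <- (q[2] - q[1]) / 0.6071
      hit <- !ok
      if (is.finite(s)) {
        # floor the offset at a 6x variance ratio: with few windows the
        # quantile distance can collapse to ~0, and artifactual
        # "high variability" is an order-of-magnitude effect
        off <- max((0.6745 + var_z) * s, log(6))
        hit <- hit | (v[r, ] > q[2] + off)
      }
      for (j in which(hit))
        mask[live[r], ((j - 1L) * w + 1L):(j * w)] <- TRUE
    }
  }
  mask
}

#' Identify bad channels from an artifact mask
#'
#' A channel is bad when strictly more than \code{threshold} (default 50%)
#' of its samples are flagged.
#'
#' @param rec An \code{eeg_recording}.
#' @param artifact_mask Logical channels x samples matrix from
#'   \code{\link{detect_artifacts}}.
#' @param threshold Fraction of flagged samples above which a channel is
#'   removed (strict inequality).
#' @return Character vector of bad channel labels (possibly empty).
#' @export
detect_bad_channels <- function(rec, artifact_mask, threshold = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.logical(artifact_mask) || !identical(dim(artifact_mask), dim(rec$data)))
    stop("`artifact_mask` must be a logical matrix with the shape of rec$data")
  frac <- rowMeans(artifact_mask)
  rec$channel_labels[frac > threshold]
}

#' Remove each subject's bad channels from both sessions
#'
#' Bad channels are removed pairwise: both sessions of a subject drop the
#' union of the two sessions' bad-channel sets, so the retained channel set
#' (and hence the edge set) is identical across sessions.
#'
#' @param session1,session2 The subject's two \code{eeg_recording}s with
#'   identical channel label sets.
#' @param bad1,bad2 Character vectors of bad channel labels per session.
#' @return A list with elements \code{session1} and \code{session2}.
#' @export
harmonize_channels <- function(session1, session2,
                               bad1 = character(0), bad2 = character(0)) {
  stopifnot(inherits(session1, "eeg_recording"),
            inherits(session2, "eeg_recording"))
  if (!setequal(session1$channel_labels, session2$channel_labels))
    stop("sessions have different channel label sets")
  drop <- union(bad1, bad2)
  keep <- setdiff(session1$channel_labels, drop)
  if (length(keep) < 2L)
    stop(sprintf("fewer than 2 channels remain after removing %d bad channels",
                 length(drop)))
  sub <- function(rec) {
    eeg_recording(rec$data[keep, , drop = FALSE], rec$sampling_rate, keep,
                  rec$subject_id, rec$session_id)
  }
  list(session1 = sub(session1), session2 = sub(session2))
}

#' Cut a recording into epochs and select a random subset
#'
#' The record is cut into consecutive non-overlapping epochs starting at the
#' first sample. Epochs containing any artifact-flagged sample are removed
#' from the candidate pool, then \code{n_select} epochs are drawn uniformly
#' without replacement (seeded); the selected epochs keep temporal order.
#'
#' @param rec A band-filtered \code{eeg_recording}.
#' @param epoch_length Epoch length in seconds (default 5).
#' @param n_select Number of epochs to keep (default 20).
#' @param seed Integer seed for the random draw; \code{NULL} leaves the RNG
#'   state untouched.
#' @param artifact_mask Optional logical channels x samples matrix; epochs
#'   overlapping flagged samples are excluded before selection.
#' @param band_name Metadata carried into the result.
#' @return A \code{\link{band_epochs}} object.
#' @export
epoch_and_select <- function(rec, epoch_length = 5, n_select = 20,
                             seed = NULL, artifact_mask = NULL,
                             band_name = NA_character_) {
  stopifnot(inherits(rec, "eeg_recording"))
  n_per <- round(epoch_length * rec$sampling_rate)
  n_cand <- ncol(rec$data) %/% n_per
  if (n_cand < 1L) stop("recording shorter than one epoch")
  starts <- (seq_len(n_cand) - 1L) * n_per + 1L
  clean <- rep(TRUE, n_cand)
  if (!is.null(artifact_mask)) {
    if (!identical(dim(artifact_mask), dim(rec$data)))
      stop("`artifact_mask` shape mismatch")
    clean <- vapply(starts, function(s)
      !any(artifact_mask[, s:(s + n_per - 1L)]), logical(1))
  }
  pool <- which(clean)
  if (length(pool) < n_select)
    stop(sprintf("only %d clean epochs available, %d requested",
                 length(pool), n_select))
  if (length(pool) == n_select) {
    sel <- pool
  } else {
    if (!is.null(seed)) {
      old <- .save_rng(); on.exit(.restore_rng(old))
      set.seed(seed)
    }
    sel <- sort(sample(pool, n_select))
  }
  ep <- array(NA_real_, dim = c(n_select, nrow(rec$data), n_per))
  for (i in seq_along(sel)) {
    s <- starts[sel[i]]
    ep[i, , ] <- rec$data[, s:(s + n_per - 1L)]
  }
  band_epochs(ep, rec$sampling_rate, epoch_length, rec$channel_labels,
              rec$subject_id, rec$session_id, band_name)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
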