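# Synthetic two-session EEG cohort generator: band-limited coupled
# oscillators with subject-specific connectivity fingerprints and a
# controllable between-session stability parameter.

#' Ring-lattice default coupling matrix
#'
#' Population-mean coupling used by \code{\link{cohort_spec}} when none is
#' given: channels sit on a ring and coupling decays with ring distance
#' (spatially proximal electrodes couple more strongly), nearest neighbours
#' at \code{peak}.
#'
#' @param n_channels Number of channels.
#' @param peak Coupling of adjacent channels (default 0.5).
#' @param decay Exponential decay length in ring-distance units.
#' @return Symmetric \code{n_channels} x \code{n_channels} matrix, zero
#'   diagonal, entries in [0, 1].
#' @export
default_coupling <- function(n_channels, peak = 0.5, decay = 2) {
  idx <- seq_len(n_channels)
  d <- outer(idx, idx, function(i, j) pmin(abs(i - j), n_channels - abs(i - j)))
  W <- peak * exp(-(d - 1) / decay)
  diag(W) <- 0
  W
}

#' Specification of a synthetic two-session cohort
#'
#' Defines the statistical structure of a simulated test-retest EEG study:
#' per-band population-mean couplings, between-subject spread
#' (\code{subject_sd}) split between a subject-level fingerprint shared
#' across edges and edge-specific deviations (\code{fingerprint_share}),
#' and the correlation of a subject's edge couplings across the two
#' sessions (\code{session_stability}).
#'
#' @param n_subjects Number of subjects (default 60, as in a typical infant
#'   test-retest cohort).
#' @param n_channels Number of EEG channels (default 32).
#' @param sampling_rate Sampling rate in Hz (default 512).
#' @param duration Seconds of signal per session (default 150, i.e. 30
#'   candidate 5-s epochs).
#' @param bands Band table (data.frame name/low/high); default the six
#'   canonical bands of \code{\link{eeg_bands}}.
#' @param coupling_base Symmetric matrix in [0, 1] with zero diagonal
#'   (recycled across bands), or a named list with one matrix per band.
#'   Default \code{\link{default_coupling}}.
#' @param subject_sd Between-subject SD of edge couplings (default 0.15,
#'   which reproduces an inter-subject COV of global alpha-band PLI of
#'   about 0.08, typical of infant sensor-space studies).
#' @param fingerprint_share Fraction of the between-subject coupling
#'   variance carried by a subject-level component common to all edges
#'   (default 0.5). Without a shared component, edge deviations average
#'   out of global connectivity as 1/sqrt(n_edges) and subjects become
#'   indistinguishable at the global level.
#' @param session_stability Correlation of a subject's coupling deviations
#'   across sessions: scalar in [0, 1], or a symmetric per-edge matrix.
#' @param noise_sd SD of additive white sensor noise (latent oscillators
#'   have unit SD per band, so \code{noise_sd = 1} is a moderately noisy
#'   recording).
#' @param phase_lag Phase lag (radians) imposed on each coupled pair; must
#'   not be a multiple of pi (a zero/antiphase lag has no phase asymmetry
#'   and yields PLI 0 by construction). Default pi/2.
#' @param seed Integer seed; expands into per-subject substreams so a
#'   subject's data do not change when \code{n_subjects} does.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_subjects = 60, n_channels = 32,
                        sampling_rate = 512, duration = 150,
                        bands = eeg_bands(),
                        coupling_base = NULL,
                        subject_sd = 0.15, fingerprint_share = 0.5,
                        session_stability = 0.8,
                        noise_sd = 1, phase_lag = pi / 2, seed = 1) {
  if (is.null(coupling_base)) coupling_base <- default_coupling(n_channels)
  if (!is.list(coupling_base))
    coupling_base <- setNames(rep(list(coupling_base), nrow(bands)), bands$name)
  spec <- structure(
    list(n_subjects = n_subjects, n_channels = n_channels,
         sampling_rate = sampling_rate, duration = duration,
         bands = bands, coupling_base = coupling_base,
         subject_sd = subject_sd, fingerprint_share = fingerprint_share,
         session_stability = session_stability,
         noise_sd = noise_sd, phase_lag = phase_lag, seed = seed),
    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' Validate a cohort specification
#'
#' @param spec A \code{cohort_spec}.
#' @return The spec, invisibly; stops on any invariant violation.
#' @export
validate_cohort_spec <- function(spec) {
  with(spec, {
    stopifnot(n_subjects >= 1, n_channels >= 2, sampling_rate > 0,
              duration > 0, subject_sd >= 0, noise_sd >= 0,
              fingerprint_share >= 0, fingerprint_share <= 1)
    num <- c(n_subjects, n_channels, sampling_rate, duration, subject_sd,
             fingerprint_share, noise_sd, phase_lag, seed)
    if (any(!is.finite(num))) stop("non-finite value in cohort spec")
    rho <- session_stability
    if (any(!is.finite(rho)) || any(rho < 0) || any(rho > 1))
      stop("session_stability must lie in [0, 1]")
    if (is.matrix(rho)) {
      if (!all(dim(rho) == c(n_channels, n_channels)) ||
          !isSymmetric(unname(rho)))
        stop("per-edge session_stability must be a symmetric n_channels matrix")
    } else if (length(rho) != 1L) {
      stop("session_stability must be a scalar or a matrix")
    }
    if (abs(sin(phase_lag)) < 1e-9)
      stop("phase_lag must not be an integer multiple of pi")
    for (nm in names(coupling_base)) {
      G <- coupling_base[[nm]]
      if (!is.matrix(G) || nrow(G) != n_channels || ncol(G) != n_channels)
        stop(sprintf("coupling_base[[%s]] has wrong dimensions", nm))
      if (!isSymmetric(unname(G))) stop("coupling_base must be symmetric")
      if (any(diag(G) != 0)) stop("coupling_base diagonal must be zero")
      if (any(G < 0 | G > 1) || any(!is.finite(G)))
        stop("coupling_base entries must lie in [0, 1]")
    }
  })
  invisible(spec)
}

# deterministic 32-bit substream seed, exact in double arithmetic
derive_seed <- function(seed, idx) {
  ((seed %% 2147483647) * 69069 + idx * 104729) %% 2147483647
}

#' Generate a synthetic two-session cohort
#'
#' For every subject, per-band edge couplings are drawn once per session as
#' \code{clip(coupling_base + subject_sd * Z, 0, 1)}, where the deviation
#' \code{Z} mixes a subject-level fingerprint with edge noise, and the
#' session-2 deviation is \code{rho * Z1 + sqrt(1 - rho^2) * Z2'} so that
#' coupling deviations correlate \code{rho = session_stability} across
#' sessions. Signals are built per band from latent narrowband oscillators
#' (band-passed white noise, unit SD): along each coupled edge the
#' higher-index channel receives the lower-index channel's latent source
#' shifted by \code{phase_lag}, with mixing weight equal to the edge
#' coupling; the receiving channel's own-source weight is
#' \code{1 - max(received couplings)}, so a strongly coupled pair is
#' dominated by the shared lagged source while channels receiving many
#' moderate edges keep a nondegenerate own signal. Bands are summed
#' and white noise of SD \code{noise_sd} added. Bit-reproducible given the
#' spec (including seed).
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @return A list of \code{\link{eeg_recording}}s of length
#'   \code{2 * n_subjects}, named \code{"S01_1"}, \code{"S01_2"}, ...;
#'   the ground-truth couplings are attached as attribute
#'   \code{"couplings"}: \code{couplings[[subject]][[session]][[band]]}.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  old <- .save_rng(); on.exit(.restore_rng(old))
  n_ch <- spec$n_channels
  n_samp <- round(spec$duration * spec$sampling_rate)
  ut <- upper.tri(matrix(0, n_ch, n_ch))
  rho <- spec$session_stability
  rho_e <- if (is.matrix(rho)) rho[ut] else rep(rho, sum(ut))

  recs <- vector("list", 2L * spec$n_subjects)
  truths <- vector("list", spec$n_subjects)
  nm <- character(length(recs))

  for (s in seq_len(spec$n_subjects)) {
    sid <- sprintf("S%02d", s)
    set.seed(derive_seed(spec$seed, s))
    # per-band coupling deviations: fingerprint + edge-specific, two
    # independent draws mixed by rho for session 2
    g <- list()
    for (b in spec$bands$name) {
      base_e <- spec$coupling_base[[b]][ut]
      z <- function() {
        sqrt(spec$fingerprint_share) * stats::rnorm(1) +
          sqrt(1 - spec$fingerprint_share) * stats::rnorm(length(base_e))
      }
      z1 <- z(); z2p <- z()
      d1 <- spec$subject_sd * z1
      d2 <- spec$subject_sd * (rho_e * z1 + sqrt(1 - rho_e^2) * z2p)
      mk <- function(dev) {
        M <- matrix(0, n_ch, n_ch)
        M[ut] <- pmin(pmax(base_e + dev, 0), 1)
        M + t(M)
      }
      g[[b]] <- list(mk(d1), mk(d2))
    }
    truths[[s]] <- list(session1 = lapply(g, `[[`, 1L),
                        session2 = lapply(g, `[[`, 2L))
    for (sess in 1:2) {
      set.seed(derive_seed(spec$seed, 100000L + 2L * s + sess))
      Y <- matrix(0, n_ch, n_samp)
      for (bi in seq_len(nrow(spec$bands))) {
        b <- spec$bands$name[bi]
        X <- matrix(stats::rnorm(n_ch * n_samp), n_ch, n_samp)
        X <- zp_bandpass(X, spec$sampling_rate,
                         spec$bands$low[bi], spec$bands$high[bi])
        X <- X / apply(X, 1L, stats::sd)
        A <- analytic_signal(X)
        L <- Re(A * exp(-1i * spec$phase_lag))   # lagged copy of each source
        G <- g[[b]][[sess]]
        Glow <- G; Glow[!ut] <- 0                # direction: low index -> high
        # own-source weight shrinks with the strongest received coupling
        # (a sum-based reduction hits zero once a channel receives many
        # moderate edges, saturating PLI and breaking monotonicity)
        own <- 1 - apply(Glow, 2L, max)
        Y <- Y + own * X + t(Glow) %*% L
      }
      if (spec$noise_sd > 0)
        Y <- Y + spec$noise_sd * matrix(stats::rnorm(n_ch * n_samp), n_ch, n_samp)
      k <- 2L * (s - 1L) + sess
      recs[[k]] <- eeg_recording(Y, spec$sampling_rate,
                                 subject_id = sid, session_id = sess)
      nm[k] <- sprintf("%s_%d", sid, sess)
    }
  }
  names(recs) <- nm
  names(truths) <- sprintf("S%02d", seq_len(spec$n_subjects))
  attr(recs, "couplings") <- truths
  attr(recs, "spec") <- spec
  recs
}

#' Ground-truth couplings of a synthetic cohort as a long table
#'
#' @param cohort Result of \code{\link{generate_cohort}}.
#' @return A data.frame with columns subject, session, band, chan_i,
#'   chan_j, weight.
#' @export
couplings_table <- function(cohort) {
  truths <- attr(cohort, "couplings")
  if (is.null(truths)) stop("cohort carries no ground-truth couplings")
  rows <- list()
  for (sid in names(truths)) {
    for (sess in 1:2) {
      bands <- truths[[sid]][[sess]]
      for (b in names(bands)) {
        G <- bands[[b]]
        ut <- which(upper.tri(G), arr.ind = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = sid, session = sess, band = b,
          chan_i = ut[, 1], chan_j = ut[, 2], weight = G[ut],
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Inject artifacts into a recording
#'
#' Adds step discontinuities ("jumps") and, for designated bad channels,
#' high-variance segments covering more than half of the channel's
#' duration, at seeded random positions. Returns the corrupted recording
#' together with the ground-truth annotation, for exercising artifact and
#' bad-channel detection.
#'
#' @param rec An \code{eeg_recording}.
#' @param bad_channel_fraction Fraction of channels made bad (rounded to a
#'   whole number of channels).
#' @param jump_rate Expected number of step artifacts per channel over the
#'   whole recording (clean channels only).
#' @param seed Integer seed.
#' @param jump_sd Step amplitude in units of the channel SD (default 50).
#' @return A list: \code{recording} (corrupted copy) and \code{truth}
#'   (list with \code{bad_channels}, \code{jumps} data.frame, and logical
#'   \code{mask} of injected-artifact samples).
#' @export
inject_artifacts <- function(rec, bad_channel_fraction = 0, jump_rate = 0,
                             seed = 1, jump_sd = 50) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (bad_channel_fraction < 0 || bad_channel_fraction > 1)
    stop("bad_channel_fraction must lie in [0, 1]")
  if (jump_rate < 0) stop("jump_rate must be nonnegative")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  x <- rec$data
  n_ch <- nrow(x); n_s <- ncol(x)
  mask <- matrix(FALSE, n_ch, n_s)
  jumps <- data.frame(channel = character(0), sample = integer(0),
                      amplitude = numeric(0), stringsAsFactors = FALSE)
  n_bad <- round(bad_channel_fraction * n_ch)
  bad_idx <- if (n_bad > 0) sample(n_ch, n_bad) else integer(0)

  for (ci in bad_idx) {
    # disjoint noisy blocks covering 60% of the duration; blocks are long
    # (1/5 of the recording) so that downstream variance windows fall
    # cleanly inside or outside them
    n_seg <- 5L
    seg_len <- n_s %/% n_seg
    segs <- sample(n_seg, 3L)
    sdc <- stats::sd(x[ci, ])
    for (sg in segs) {
      idx <- ((sg - 1L) * seg_len + 1L):(sg * seg_len)
      x[ci, idx] <- x[ci, idx] + stats::rnorm(length(idx), sd = 10 * sdc)
      mask[ci, idx] <- TRUE
    }
  }
  if (jump_rate > 0) {
    for (ci in setdiff(seq_len(n_ch), bad_idx)) {
      n_j <- stats::rpois(1, jump_rate)
      if (n_j == 0) next
      pos <- sample(2:(n_s - 1L), min(n_j, n_s - 2L))
      sdc <- stats::sd(x[ci, ])
      for (p in pos) {
        amp <- jump_sd * sdc * sample(c(-1, 1), 1)
        x[ci, p:n_s] <- x[ci, p:n_s] + amp
        mask[ci, p] <- TRUE
        jumps <- rbind(jumps, data.frame(
          channel = rec$channel_labels[ci], sample = p, amplitude = amp,
          stringsAsFactors = FALSE))
      }
    }
  }
  list(recording = eeg_recording(x, rec$sampling_rate, rec$channel_labels,
                                 rec$subject_id, rec$session_id),
       truth = list(bad_channels = rec$channel_labels[sort(bad_idx)],
                    jumps = jumps, mask = mask))
}
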