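# Phase-based connectivity: analytic signal, PLI, debiased weighted PLI.

#' Analytic signal via the Hilbert transform
#'
#' FFT-based analytic signal of each channel (one-sided spectrum doubling).
#' Input should be band-limited; no padding is applied, so a few samples at
#' the epoch edges carry transform edge effects.
#'
#' @param x Numeric vector, or channels x samples matrix (one signal per row).
#' @return Complex vector/matrix of the same shape.
#' @export
analytic_signal <- function(x) {
  if (is.matrix(x)) return(t(apply(x, 1L, analytic_signal)))
  n <- length(x)
  if (all(x == 0)) stop("analytic signal undefined for an all-zero channel")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of band-limited signals
#'
#' Phase of the analytic signal, in (-pi, pi].
#'
#' @param epoch Numeric channels x samples matrix (or a vector).
#' @return Matrix/vector of phases in radians.
#' @export
instantaneous_phase <- function(epoch) {
  Arg(analytic_signal(epoch))
}

#' Phase lag index of one signal pair
#'
#' \code{PLI = |mean_k sign(sin(phi_a(t_k) - phi_b(t_k)))|}: the absolute
#' mean sign of the instantaneous phase difference. Indexes the consistency
#' of one signal leading or lagging the other; exactly zero for a constant
#' zero phase difference (the volume-conduction case) and 1 for a constant
#' nonzero lag. Range [0, 1].
#'
#' @param phase_a,phase_b Numeric phase vectors (radians) of equal length.
#' @return Scalar PLI in [0, 1].
#' @export
pli_pair <- function(phase_a, phase_b) {
  if (length(phase_a) != length(phase_b))
    stop("phase vectors differ in length")
  if (length(phase_a) < 1L) stop("empty phase vectors")
  abs(mean(sign(sin(phase_a - phase_b))))
}

#' Debiased weighted phase lag index of one signal pair
#'
#' Weighted PLI-square with finite-sample debiasing, computed from the
#' per-sample imaginary cross-spectral terms
#' \code{I_k = Im(a_k * Conj(b_k))}:
#' \deqn{dwPLI = ((\sum I)^2 - \sum I^2) / ((\sum |I|)^2 - \sum I^2)}
#' Weighting by |I| suppresses near-zero-lag contributions (noise-driven
#' false positives); the debiasing term makes the estimator unbiased at
#' zero true coupling and allows negative values, so the range is [-1, 1].
#' When every \code{I_k} is zero (exactly zero-lag signals) the denominator
#' vanishes and the value is defined as 0, with a warning.
#'
#' @param analytic_a,analytic_b Complex analytic-signal vectors of equal
#'   length (samples pooled over epochs).
#' @return Scalar dwPLI in [-1, 1].
#' @export
dwpli_pair <- function(analytic_a, analytic_b) {
  if (length(analytic_a) != length(analytic_b))
    stop("analytic-signal vectors differ in length")
  I <- Im(analytic_a * Conj(analytic_b))
  s <- sum(I); q <- sum(I^2); a <- sum(abs(I))
  den <- a^2 - q
  if (den == 0) {
    warning("all imaginary cross-spectral terms are zero (zero-lag pair); dwPLI defined as 0")
    return(0)
  }
  (s^2 - q) / den
}

#' Construct a connectivity matrix container
#'
#' @param values Symmetric channels x channels matrix, zero diagonal.
#' @param method \code{"pli"} or \code{"dwpli"}.
#' @param channel_labels Channel names.
#' @param n_epochs Number of epochs the estimate used.
#' @param subject_id,session_id,band_name Provenance metadata.
#' @return An object of class \code{conn_matrix}.
#' @export
conn_matrix <- function(values, method, channel_labels = NULL,
                        n_epochs = NA_integer_,
                        subject_id = NA_character_, session_id = NA_integer_,
                        band_name = NA_character_) {
  method <- match.arg(method, c("pli", "dwpli"))
  if (!isSymmetric(unname(values), tol = 1e-12))
    stop("`values` must be symmetric")
  if (any(abs(diag(values)) > 0)) stop("diagonal must be zero")
  rng <- if (method == "pli") c(0, 1) else c(-1, 1)
  if (any(values < rng[1] - 1e-9 | values > rng[2] + 1e-9))
    stop(sprintf("%s values outside [%g, %g]", method, rng[1], rng[2]))
  if (is.null(channel_labels))
    channel_labels <- sprintf("Ch%02d", seq_len(nrow(values)))
  dimnames(values) <- list(channel_labels, channel_labels)
  structure(
    list(values = values, method = method,
         channel_labels = as.character(channel_labels),
         n_epochs = n_epochs, subject_id = subject_id,
         session_id = session_id, band_name = band_name),
    class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<conn_matrix> %s, subject %s session %s band %s: %d channels (%d pairs), %s epochs\n",
              toupper(x$method), x$subject_id, x$session_id, x$band_name,
              nrow(x$values), nrow(x$values) * (nrow(x$values) - 1) / 2,
              x$n_epochs))
  invisible(x)
}

#' Connectivity matrix from band-limited epochs
#'
#' For every unordered channel pair, PLI is computed per epoch from the
#' instantaneous phases and averaged across epochs; dwPLI pools the
#' per-sample imaginary cross-spectral terms of all epochs before forming
#' the debiased ratio (this pooling is where the estimator's debiasing
#' with respect to the number of epochs acts).
#'
#' @param epochs A \code{\link{band_epochs}} object with at least one epoch
#'   and two channels.
#' @param method \code{"pli"} or \code{"dwpli"}.
#' @return A \code{\link{conn_matrix}}.
#' @export
connectivity_matrix <- function(epochs, method = c("pli", "dwpli")) {
  stopifnot(inherits(epochs, "band_epochs"))
  method <- match.arg(method)
  d <- dim(epochs$epochs)
  n_ep <- d[1]; n_ch <- d[2]
  if (n_ch < 2L) stop("need at least 2 channels")
  pairs <- which(upper.tri(matrix(0, n_ch, n_ch)), arr.ind = TRUE)
  M <- matrix(0, n_ch, n_ch)
  if (method == "pli") {
    acc <- numeric(nrow(pairs))
    for (e in seq_len(n_ep)) {
      ph <- instantaneous_phase(matrix(epochs$epochs[e, , ], nrow = n_ch))
      for (p in seq_len(nrow(pairs))) {
        i <- pairs[p, 1]; j <- pairs[p, 2]
        acc[p] <- acc[p] + pli_pair(ph[i, ], ph[j, ])
      }
    }
    vals <- acc / n_ep
  } else {
    S <- numeric(nrow(pairs)); Q <- numeric(nrow(pairs)); A <- numeric(nrow(pairs))
    for (e in seq_len(n_ep)) {
      an <- analytic_signal(matrix(epochs$epochs[e, , ], nrow = n_ch))
      for (p in seq_len(nrow(pairs))) {
        i <- pairs[p, 1]; j <- pairs[p, 2]
        I <- Im(an[i, ] * Conj(an[j, ]))
        S[p] <- S[p] + sum(I)
        Q[p] <- Q[p] + sum(I^2)
        A[p] <- A[p] + sum(abs(I))
      }
    }
    den <- A^2 - Q
    vals <- ifelse(den == 0, 0, (S^2 - Q) / den)
    if (any(den == 0))
      warning(sprintf("%d zero-lag pair(s); dwPLI defined as 0", sum(den == 0)))
  }
  M[pairs] <- vals
  M <- M + t(M)
  conn_matrix(M, method, epochs$channel_labels, n_ep,
              epochs$subject_id, epochs$session_id, epochs$band_name)
}
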