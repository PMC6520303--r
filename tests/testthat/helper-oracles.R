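# Independent oracles and small fixture builders used across test files.

# single narrow analysis band used by most synthetic-cohort tests
alpha_band <- function() data.frame(name = "alpha", low = 8, high = 12)

# brute-force Onnela clustering: enumerate all ordered triples
oracle_clustering <- function(W) {
  n <- nrow(W)
  Wn <- W / max(W)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(W[i, ] > 0)
    if (k < 2) next
    t_i <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == i || h == i || j == h) next
      t_i <- t_i + (Wn[i, j] * Wn[i, h] * Wn[j, h])^(1 / 3)
    }
    t_i <- t_i / 2
    ci[i] <- 2 * t_i / (k * (k - 1))
  }
  mean(ci)
}

# all-pairs shortest paths by Floyd-Warshall on inverse-weight lengths
oracle_path_length <- function(W) {
  n <- nrow(W)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[W > 0] <- 1 / W[W > 0]
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  off <- d[row(d) != col(d)]
  stopifnot(all(is.finite(off)))
  mean(off)
}

# two-way ANOVA mean squares via stats::aov, plugged into the ICC formula
oracle_icc_twoway <- function(tab) {
  n <- nrow(tab); k <- ncol(tab)
  df <- data.frame(value = as.vector(tab),
                   subject = factor(rep(seq_len(n), k)),
                   session = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(value ~ subject + session, data = df))[[1]][, "Mean Sq"]
  MSr <- ms[1]; MSe <- ms[3]
  (MSr - MSe) / (MSr + (k - 1) * MSe)
}

oracle_icc_oneway <- function(tab) {
  n <- nrow(tab); k <- ncol(tab)
  df <- data.frame(value = as.vector(tab),
                   subject = factor(rep(seq_len(n), k)))
  ms <- summary(stats::aov(value ~ subject, data = df))[[1]][, "Mean Sq"]
  (ms[1] - ms[2]) / (ms[1] + (k - 1) * ms[2])
}

# random symmetric nonnegative weight matrix with full support
random_weight_matrix <- function(n, min_w = 0.05) {
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- stats::runif(n * (n - 1) / 2, min_w, 1)
  W + t(W)
}

# conn_matrix built straight from a weight matrix (no signals involved)
make_cm <- function(W, subject = "S01", session = 1L, band = "alpha",
                    method = "pli") {
  conn_matrix(W, method, subject_id = subject, session_id = session,
              band_name = band)
}

# cohort of conn_matrix pairs drawn around per-subject edge levels:
# session2 reuses session1 edges where `stable_mask` is TRUE and redraws
# the rest; independent measurement noise on both sessions
make_matrix_cohort <- function(n_sub, n_ch, stable_mask = NULL,
                               noise = 0.02, seed = 1) {
  set.seed(seed)
  nE <- n_ch * (n_ch - 1) / 2
  if (is.null(stable_mask)) stable_mask <- rep(TRUE, nE)
  base <- stats::runif(nE, 0.2, 0.8)
  s1 <- list(); s2 <- list()
  for (s in seq_len(n_sub)) {
    e1 <- pmin(pmax(base + stats::rnorm(nE, sd = 0.1), 0), 1)
    e2 <- ifelse(stable_mask, e1,
                 pmin(pmax(base + stats::rnorm(nE, sd = 0.1), 0), 1))
    mk <- function(e) {
      W <- matrix(0, n_ch, n_ch)
      W[upper.tri(W)] <- pmin(pmax(e + stats::rnorm(nE, sd = noise), 0), 1)
      W + t(W)
    }
    sid <- sprintf("S%02d", s)
    s1[[sid]] <- make_cm(mk(e1), sid, 1L)
    s2[[sid]] <- make_cm(mk(e2), sid, 2L)
  }
  list(s1 = s1, s2 = s2)
}

# phase unwrapping for slope checks
unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], d))
}
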