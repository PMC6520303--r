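# Test-retest reliability statistics: matrix correlations, global and
# unit-wise ICC(3,1), coefficient of variation, bootstrap confidence
# intervals, top-percentile edge selection.

.upper_vec <- function(m) {
  if (inherits(m, "conn_matrix")) m <- m$values
  m[upper.tri(m)]
}

#' Pearson correlation of two connectivity matrices
#'
#' Correlation between the vectorized upper triangles (diagonal excluded)
#' of a subject's session-1 and session-2 matrices: the most basic,
#' matrix-level reliability.
#'
#' @param m1,m2 \code{\link{conn_matrix}} objects (same channels, band and
#'   method) or plain symmetric matrices of equal dimension.
#' @return Pearson r.
#' @export
matrix_correlation <- function(m1, m2) {
  if (inherits(m1, "conn_matrix") && inherits(m2, "conn_matrix")) {
    if (!identical(m1$channel_labels, m2$channel_labels))
      stop("matrices have different channel sets")
    if (!identical(m1$method, m2$method))
      stop("matrices computed with different methods")
    if (!identical(m1$band_name, m2$band_name) &&
        !(is.na(m1$band_name) && is.na(m2$band_name)))
      stop("matrices from different frequency bands")
  }
  v1 <- .upper_vec(m1); v2 <- .upper_vec(m2)
  if (length(v1) != length(v2)) stop("matrix dimensions differ")
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("zero variance in a connectivity vector; correlation undefined")
  stats::cor(v1, v2)
}

#' Global connectivity of a matrix
#'
#' Mean over all unique electrode pairs (upper triangle, diagonal
#' excluded). The number of retained pairs varies per subject after
#' bad-channel removal and is recorded by the pipeline.
#'
#' @param m A \code{\link{conn_matrix}} or symmetric matrix.
#' @return Scalar mean connectivity.
#' @export
global_connectivity <- function(m) mean(.upper_vec(m))

#' Intraclass correlation ICC(3,1)
#'
#' Two-way mixed-effects, consistency, single-measure ICC of a
#' subjects x measurements table:
#' \deqn{ICC = (MS_r - MS_e) / (MS_r + (k - 1) MS_e)}
#' with \code{MS_r} the between-subjects mean square and \code{MS_e} the
#' residual mean square after removing subject and session effects (so a
#' constant additive session shift does not lower the ICC). The literal
#' one-way random-effects variant (session effects absorbed into error) is
#' available via \code{model = "oneway"}. Values can be negative and are
#' never clamped.
#'
#' @param values Numeric matrix, subjects x k measurements (k >= 2), no
#'   missing cells.
#' @param model \code{"twoway"} (default, ICC(3,1)) or \code{"oneway"}
#'   (ICC(1,1)).
#' @return Scalar ICC (<= 1, possibly negative).
#' @export
icc <- function(values, model = c("twoway", "oneway")) {
  model <- match.arg(model)
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (n < 3L) stop("need at least 3 subjects")
  if (k < 2L) stop("need at least 2 measurements per subject")
  if (any(!is.finite(values))) stop("missing or non-finite cells")
  grand <- mean(values)
  row_m <- rowMeans(values)
  col_m <- colMeans(values)
  SSr <- k * sum((row_m - grand)^2)
  MSr <- SSr / (n - 1)
  if (model == "twoway") {
    SSc <- n * sum((col_m - grand)^2)
    SSt <- sum((values - grand)^2)
    SSe <- SSt - SSr - SSc
    MSe <- SSe / ((n - 1) * (k - 1))
  } else {
    SSw <- sum((values - row_m)^2)   # row_m recycles down columns
    MSe <- SSw / (n * (k - 1))
  }
  if (MSe <= .Machine$double.eps * max(1, abs(grand))^2) {
    if (MSr > 0) {
      warning("zero residual variance: every subject measured identically; ICC = 1")
      return(1)
    }
    stop("table has no subject or residual variance; ICC undefined")
  }
  (MSr - MSe) / (MSr + (k - 1) * MSe)
}

#' Coefficient of variation across subjects
#'
#' Sample standard deviation divided by the mean: the inter-subject
#' variability of a connectivity or graph measure.
#'
#' @param values Numeric vector of per-subject values with nonzero mean.
#' @return Scalar COV.
#' @export
cov_subjects <- function(values) {
  if (any(!is.finite(values))) stop("non-finite values")
  m <- mean(values)
  if (m == 0) stop("zero mean; COV undefined")
  stats::sd(values) / m
}

#' Percentile bootstrap confidence interval over subjects
#'
#' Resamples subjects (rows) with replacement, keeping each subject's
#' session pair intact, recomputes the statistic, and returns the
#' percentile interval.
#'
#' @param statistic Function mapping a subjects x k matrix (or data.frame)
#'   to a scalar.
#' @param data Subjects x k matrix; rows are resampled.
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param seed Integer seed; \code{NULL} leaves the RNG state untouched.
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector \code{c(lo, hi)}.
#' @export
bootstrap_ci <- function(statistic, data, n_boot = 10000, seed = NULL,
                         conf = 0.95) {
  data <- as.matrix(data)
  if (n_boot < 1) stop("n_boot must be >= 1")
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  n <- nrow(data)
  stats_b <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    tryCatch(statistic(data[idx, , drop = FALSE]),
             error = function(e) NA_real_,
             warning = function(w) suppressWarnings(
               statistic(data[idx, , drop = FALSE])))
  }, numeric(1))
  bad <- sum(!is.finite(stats_b))
  if (bad > n_boot / 2)
    stop(sprintf("statistic undefined on %d of %d resamples", bad, n_boot))
  a <- (1 - conf) / 2
  q <- stats::quantile(stats_b, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  c(lo = q[1], hi = q[2])
}

# assemble a subjects x 2 table of a per-matrix statistic
.session_table <- function(session1, session2, stat) {
  if (length(session1) != length(session2))
    stop("session lists differ in length")
  n <- length(session1)
  out <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    out[i, 1] <- stat(session1[[i]])
    out[i, 2] <- stat(session2[[i]])
  }
  rownames(out) <- vapply(session1, function(m)
    if (inherits(m, "conn_matrix")) as.character(m$subject_id) else NA_character_,
    character(1))
  out
}

#' Global-connectivity ICC of a cohort
#'
#' Builds the subjects x 2 table of global connectivity values (session 1
#' vs session 2) for one band and method, computes ICC(3,1), and attaches
#' a bootstrap confidence interval.
#'
#' @param session1,session2 Lists of \code{\link{conn_matrix}} objects,
#'   one per subject, aligned by position.
#' @param n_boot Bootstrap resamples for the CI (default 10000).
#' @param seed Integer seed for the bootstrap.
#' @param model ICC model, see \code{\link{icc}}.
#' @return List: \code{icc}, \code{ci} (lo, hi), \code{table}.
#' @export
icc_global <- function(session1, session2, n_boot = 10000, seed = NULL,
                       model = "twoway") {
  tab <- .session_table(session1, session2, global_connectivity)
  est <- icc(tab, model = model)
  ci <- bootstrap_ci(function(d) icc(d, model = model), tab,
                     n_boot = n_boot, seed = seed)
  list(icc = est, ci = ci, table = tab)
}

#' Unit-wise (per-edge) ICC of a cohort
#'
#' One ICC per electrode pair across subjects (session 1 vs session 2),
#' summarized by the median (the per-edge ICC distribution is typically
#' skewed, so the median is the appropriate single reliability value).
#'
#' @param session1,session2 Lists of \code{\link{conn_matrix}} objects
#'   with a common channel set, aligned by subject.
#' @param model ICC model, see \code{\link{icc}}.
#' @return List: \code{per_edge} data.frame (chan_i, chan_j, icc),
#'   \code{median}, \code{n_edges}.
#' @export
icc_unitwise <- function(session1, session2, model = "twoway") {
  if (length(session1) != length(session2))
    stop("session lists differ in length")
  labels <- session1[[1]]$channel_labels
  for (m in c(session1, session2))
    if (!identical(m$channel_labels, labels))
      stop("matrices do not share a common channel set")
  n_ch <- length(labels)
  ut <- which(upper.tri(matrix(0, n_ch, n_ch)), arr.ind = TRUE)
  n_sub <- length(session1)
  v1 <- vapply(session1, .upper_vec, numeric(nrow(ut)))
  v2 <- vapply(session2, .upper_vec, numeric(nrow(ut)))
  iccs <- vapply(seq_len(nrow(ut)), function(e) {
    tryCatch(icc(cbind(v1[e, ], v2[e, ]), model = model),
             error = function(err) NA_real_)
  }, numeric(1))
  per_edge <- data.frame(chan_i = labels[ut[, 1]], chan_j = labels[ut[, 2]],
                         icc = iccs, stringsAsFactors = FALSE)
  list(per_edge = per_edge,
       median = stats::median(iccs, na.rm = TRUE),
       n_edges = nrow(ut))
}

#' Select the strongest edges of the grand-average network
#'
#' Averages all subjects' matrices over both sessions and masks the edges
#' in the top \code{percentile} percent by strength. The cutoff keeps at
#' least \code{ceiling(percentile/100 * n_edges)} edges; ties at the
#' cutoff are all included (with a warning when that enlarges the set).
#'
#' @param session1,session2 Lists of \code{\link{conn_matrix}} objects
#'   with a common channel set.
#' @param percentile Top percentage of edges to keep, in (0, 100);
#'   default 25.
#' @return Logical symmetric channels x channels mask (TRUE = selected).
#' @export
top_percentile_edges <- function(session1, session2, percentile = 25) {
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must lie in (0, 100)")
  mats <- c(session1, session2)
  labels <- mats[[1]]$channel_labels
  avg <- Reduce(`+`, lapply(mats, function(m) m$values)) / length(mats)
  n_ch <- nrow(avg)
  ut <- upper.tri(avg)
  w <- avg[ut]
  m_target <- ceiling(percentile / 100 * length(w))
  cutoff <- sort(w, decreasing = TRUE)[m_target]
  sel <- w >= cutoff
  if (sum(sel) > m_target)
    warning(sprintf("ties at the cutoff: %d edges selected (target %d)",
                    sum(sel), m_target))
  mask <- matrix(FALSE, n_ch, n_ch, dimnames = list(labels, labels))
  mask[ut] <- sel
  mask <- mask | t(mask)
  mask
}

#' Reliability label for an ICC value
#'
#' Conventional interpretation bins: below 0.4 low, 0.4-0.6 mediocre,
#' 0.6-0.75 good, above 0.75 excellent.
#'
#' @param icc_value Numeric vector of ICC values.
#' @return Character vector of labels.
#' @export
classify_reliability <- function(icc_value) {
  cut(icc_value, breaks = c(-Inf, 0.4, 0.6, 0.75, Inf),
      labels = c("low", "mediocre", "good", "excellent"),
      right = FALSE) |> as.character()
}
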