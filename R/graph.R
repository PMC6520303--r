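# Weighted graph characteristics of full (unthresholded) connectivity
# matrices, with random-surrogate normalization.

.check_weight_matrix <- function(W) {
  if (!is.matrix(W) || !isSymmetric(unname(W), tol = 1e-10))
    stop("weight matrix must be symmetric")
  if (any(abs(diag(W)) > 0)) stop("weight matrix diagonal must be zero")
  if (any(W < 0))
    stop("negative weights: graph metrics are defined for nonnegative ",
         "connectivity (PLI) matrices; dwPLI matrices are not valid input")
  if (any(!is.finite(W))) stop("non-finite weights")
  invisible(W)
}

#' Weighted average clustering coefficient
#'
#' Onnela-style weighted clustering: weights are scaled by the network
#' maximum, node triangle intensity is
#' \code{t_i = 1/2 * sum_jh (w_ij w_ih w_jh)^(1/3)} over scaled weights,
#' and \code{Cw = mean_i 2 t_i / (k_i (k_i - 1))} with \code{k_i} the
#' number of nonzero-weight neighbours; nodes with fewer than two
#' neighbours contribute 0.
#'
#' @param W Symmetric nonnegative matrix with zero diagonal (a PLI
#'   connectivity matrix, or its \code{$values}).
#' @return Scalar \code{Cw >= 0}.
#' @export
clustering_coefficient <- function(W) {
  if (inherits(W, "conn_matrix")) W <- W$values
  .check_weight_matrix(W)
  n <- nrow(W)
  mx <- max(W)
  if (mx == 0) return(0)
  Wn <- (W / mx)^(1 / 3)
  t_i <- diag(Wn %*% Wn %*% Wn) / 2
  k <- rowSums(W > 0)
  ci <- ifelse(k >= 2, 2 * t_i / (k * (k - 1)), 0)
  mean(ci)
}

#' Weighted characteristic path length
#'
#' Mean shortest-path distance over all ordered node pairs, with edge
#' length the inverse connection weight (\code{l_ij = 1/w_ij}), the
#' convention of the brain connectivity toolbox:
#' \code{Lw = 1/n * sum_i sum_{j != i} d_ij / (n - 1)}.
#'
#' @param W Symmetric nonnegative matrix with zero diagonal; the graph of
#'   its nonzero weights must be connected.
#' @return Scalar \code{Lw > 0}.
#' @export
characteristic_path_length <- function(W) {
  if (inherits(W, "conn_matrix")) W <- W$values
  .check_weight_matrix(W)
  n <- nrow(W)
  Lmat <- W
  Lmat[W > 0] <- 1 / W[W > 0]
  g <- igraph::graph_from_adjacency_matrix(Lmat, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, algorithm = "dijkstra")
  off <- d[row(d) != col(d)]
  if (any(!is.finite(off))) stop("graph is disconnected; Lw undefined")
  mean(off)
}

#' Normalize graph metrics against weight-permuted surrogates
#'
#' The null model shuffles the upper-triangle weights uniformly (symmetry
#' restored, diagonal kept zero), preserving the weight distribution and
#' hence global connectivity while destroying topology. \code{C_rand} and
#' \code{L_rand} are means over \code{n_surrogates} such surrogates;
#' normalized metrics are observed / surrogate-mean.
#'
#' @param W Symmetric nonnegative matrix (or \code{conn_matrix}).
#' @param n_surrogates Number of surrogates (default 100).
#' @param seed Integer seed for the permutations; \code{NULL} leaves the
#'   RNG state untouched.
#' @return List with \code{Cw_nrm}, \code{Lw_nrm}, \code{C_rand},
#'   \code{L_rand}.
#' @export
surrogate_normalize <- function(W, n_surrogates = 100, seed = NULL) {
  if (inherits(W, "conn_matrix")) W <- W$values
  .check_weight_matrix(W)
  if (n_surrogates < 1) stop("n_surrogates must be >= 1")
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  n <- nrow(W)
  ut <- upper.tri(W)
  w <- W[ut]
  cs <- numeric(n_surrogates); ls <- numeric(n_surrogates)
  for (k in seq_len(n_surrogates)) {
    S <- matrix(0, n, n)
    S[ut] <- sample(w)
    S <- S + t(S)
    cs[k] <- clustering_coefficient(S)
    ls[k] <- characteristic_path_length(S)
  }
  C_rand <- mean(cs); L_rand <- mean(ls)
  list(Cw_nrm = clustering_coefficient(W) / C_rand,
       Lw_nrm = characteristic_path_length(W) / L_rand,
       C_rand = C_rand, L_rand = L_rand)
}

#' Small-worldness index
#'
#' \code{SWI = (Cw / C_rand) / (Lw / L_rand)}: the ratio of normalized
#' clustering to normalized path length. Values above 1 indicate
#' simultaneous high clustering and short paths relative to the random
#' null; values below 1 do occur in sensor-space EEG networks.
#'
#' @param Cw_nrm,Lw_nrm Normalized clustering coefficient and path length.
#' @return Scalar SWI.
#' @export
small_worldness <- function(Cw_nrm, Lw_nrm) {
  if (!is.finite(Lw_nrm) || Lw_nrm == 0)
    stop("normalized path length must be nonzero")
  Cw_nrm / Lw_nrm
}

#' All graph metrics of one connectivity matrix
#'
#' Computes \code{Cw}, \code{Lw}, their surrogate-normalized forms (one
#' shared surrogate ensemble), and the small-worldness index.
#'
#' @param cm A \code{\link{conn_matrix}} with method \code{"pli"} (dwPLI
#'   matrices carry negative weights and are rejected), or a plain
#'   nonnegative weight matrix.
#' @param n_surrogates Surrogates for normalization (default 100).
#' @param seed Integer seed for the surrogate ensemble.
#' @return A one-row data.frame: subject, session, band, Cw, Lw, Cw_nrm,
#'   Lw_nrm, SWI, n_surrogates, surrogate_seed.
#' @export
graph_metrics <- function(cm, n_surrogates = 100, seed = NULL) {
  meta <- if (inherits(cm, "conn_matrix"))
    list(subject = cm$subject_id, session = cm$session_id, band = cm$band_name)
  else list(subject = NA_character_, session = NA_integer_, band = NA_character_)
  W <- if (inherits(cm, "conn_matrix")) cm$values else cm
  cw <- clustering_coefficient(W)
  lw <- characteristic_path_length(W)
  nrm <- surrogate_normalize(W, n_surrogates = n_surrogates, seed = seed)
  data.frame(subject = meta$subject, session = meta$session, band = meta$band,
             Cw = cw, Lw = lw, Cw_nrm = nrm$Cw_nrm, Lw_nrm = nrm$Lw_nrm,
             SWI = small_worldness(nrm$Cw_nrm, nrm$Lw_nrm),
             n_surrogates = n_surrogates,
             surrogate_seed = if (is.null(seed)) NA_integer_ else seed,
             stringsAsFactors = FALSE)
}
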