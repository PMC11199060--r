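# Similarity network fusion: nonlinear cross-diffusion of per-view
# transition kernels (full + K-nearest-neighbour local) until the views
# agree on one network. This follows the canonical SNF construction; the
# kernels and update rule are re-derived here rather than wrapped from an
# external implementation.

#' SNF hyperparameters
#'
#' @param K Neighbourhood size for the local kernel and the kernel
#'   bandwidth; must satisfy 1 <= K <= n-1 (capped at n-1 at run time).
#' @param mu Kernel scale; typical range 0.3-0.8.
#' @param T Number of cross-diffusion iterations.
#' @param eps_reg Small positive regulariser added to the local bandwidth to
#'   avoid division by zero on duplicate points.
#' @return A `fusion_params` object.
#' @export
fusion_params <- function(K = 20L, mu = 0.5, T = 20L, eps_reg = 1e-8) {
  .assert_count(K, "K"); .assert_count(T, "T")
  if (mu <= 0) stop_idsn("'mu' must be > 0")
  if (eps_reg <= 0) stop_idsn("'eps_reg' must be > 0")
  obj <- list(K = as.integer(K), mu = mu, T = as.integer(T),
              eps_reg = eps_reg)
  class(obj) <- "fusion_params"
  obj
}

#' Convert a similarity matrix to a distance matrix
#'
#' `d_ij = sqrt(2 * (1 - s_ij))`, the Euclidean distance between unit
#' vectors with cosine `s_ij`; zero diagonal.
#'
#' @param net A [similarity_network()] on similarity scale.
#' @return Symmetric numeric distance matrix with the network's dimnames.
#' @export
similarity_to_distance <- function(net) {
  s <- net$matrix
  if (net$scale != "similarity" || any(s < 0) || any(s > 1 + 1e-12))
    stop_idsn("similarity_to_distance needs similarity scale with entries in [0,1]")
  d <- sqrt(2 * pmax(1 - s, 0))   # matrix first so pmax keeps dims
  diag(d) <- 0
  (d + t(d)) / 2
}

#' Scaled-exponential affinity kernel
#'
#' `W_ij = exp(-d_ij^2 / (mu * eps_ij))` with local bandwidth
#' `eps_ij = (mean_i + mean_j + d_ij)/3 + eps_reg`, where `mean_i` is the
#' mean distance from i to its K nearest neighbours (excluding i).
#' Self-affinity is 1.
#'
#' @param d Symmetric distance matrix with zero diagonal.
#' @param params A [fusion_params()].
#' @return Symmetric affinity matrix W with unit diagonal.
#' @export
affinity_matrix <- function(d, params = fusion_params()) {
  n <- nrow(d)
  if (params$K >= n) stop_idsn("K = %d must be < n = %d", params$K, n)
  mean_knn <- vapply(seq_len(n), function(i) {
    di <- sort(d[i, -i])[seq_len(params$K)]
    mean(di)
  }, numeric(1))
  eps <- (outer(mean_knn, mean_knn, "+") + d) / 3 + params$eps_reg
  W <- exp(-d^2 / (params$mu * eps))
  diag(W) <- 1
  (W + t(W)) / 2
}

#' Full transition kernel
#'
#' Row-stochastic matrix giving half the mass to the diagonal:
#' `P_ij = W_ij / (2 * sum_{k != i} W_ik)` for j != i, `P_ii = 1/2`.
#'
#' @param W Affinity matrix.
#' @param ids Optional drug ids for error messages.
#' @return Row-stochastic matrix P.
#' @export
full_kernel <- function(W, ids = rownames(W)) {
  n <- nrow(W)
  offsum <- rowSums(W) - diag(W)
  if (any(offsum <= 0)) {
    bad <- which(offsum <= 0)[[1]]
    stop_idsn("isolated drug with zero off-diagonal affinity: %s",
              if (!is.null(ids)) ids[[bad]] else as.character(bad))
  }
  P <- W / (2 * offsum)
  diag(P) <- 0.5
  P
}

#' Local (K-nearest-neighbour) transition kernel
#'
#' `S_ij = W_ij / sum_{k in N_i} W_ik` for j in the K nearest neighbours of
#' i (by affinity, excluding i), 0 elsewhere. Ties at the K-th neighbour are
#' broken by position in the id order, i.e. lexicographic when ids are
#' sorted, so neighbour sets are deterministic across platforms.
#'
#' @param W Affinity matrix.
#' @param K Neighbourhood size, K < n.
#' @return Row-stochastic sparse-support matrix S.
#' @export
local_kernel <- function(W, K) {
  n <- nrow(W)
  if (K >= n) stop_idsn("K = %d must be < n = %d", K, n)
  S <- matrix(0, n, n, dimnames = dimnames(W))
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    # order(): descending affinity, ties broken by index (id order)
    nb <- cand[order(-W[i, cand], cand)][seq_len(K)]
    S[i, nb] <- W[i, nb] / sum(W[i, nb])
  }
  S
}

#' Fuse similarity networks by cross-diffusion (SNF)
#'
#' Converts each view to distances, builds per-view affinity, full and local
#' kernels, then iterates for `T` rounds: each view's status matrix is
#' diffused through its own local kernel against the average status of the
#' other views, and re-normalised with the full-kernel rule. The fused
#' network is the view average, symmetrised; off-diagonal entries are
#' rescaled by their maximum and the diagonal set to 1 so the output is a
#' similarity in \[0, 1\] like its inputs.
#'
#' @param views List of >= 2 [similarity_network()] objects on identical id
#'   sets in identical order.
#' @param params A [fusion_params()]; `K` is capped at n-1.
#' @param meta Metadata stored on the fused network.
#' @return A [similarity_network()] with `source = "fused"`; element
#'   `meta$diagnostics` holds the per-iteration mean absolute change of each
#'   view's status matrix and a convergence flag (tolerance 1e-6).
#' @export
snf <- function(views, params = fusion_params(), meta = list()) {
  if (length(views) < 2L) stop_idsn("snf needs at least two views")
  ids <- .check_same_ids(views)
  n <- length(ids)
  params$K <- min(params$K, n - 1L)
  Ps <- list(); Ss <- list()
  for (v in seq_along(views)) {
    d <- similarity_to_distance(views[[v]])
    W <- affinity_matrix(d, params)
    Ps[[v]] <- full_kernel(W, ids)
    Ss[[v]] <- local_kernel(W, params$K)
  }
  nv <- length(views)
  change <- matrix(NA_real_, params$T, nv)
  for (t in seq_len(params$T)) {
    new_Ps <- Ps
    for (v in seq_len(nv)) {
      others <- Reduce(`+`, Ps[-v]) / (nv - 1)
      P <- Ss[[v]] %*% others %*% t(Ss[[v]])
      P <- (P + t(P)) / 2
      # re-apply the full-kernel row normalisation to keep P a status matrix
      offsum <- rowSums(P) - diag(P)
      offsum[offsum <= 0] <- .Machine$double.eps
      P <- P / (2 * offsum)
      diag(P) <- 0.5
      change[t, v] <- mean(abs(P - Ps[[v]]))
      new_Ps[[v]] <- P
    }
    Ps <- new_Ps
  }
  fused <- Reduce(`+`, Ps) / nv
  fused <- (fused + t(fused)) / 2
  off <- fused; diag(off) <- 0
  mx <- max(off)
  if (mx > 0) fused <- off / mx else fused <- off
  diag(fused) <- 1
  meta$diagnostics <- list(change = change,
                           converged = all(change[params$T, ] < 1e-6))
  similarity_network(fused, ids = ids, source = "fused",
                     scale = "similarity", meta = meta)
}
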