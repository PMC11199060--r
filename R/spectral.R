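# Spectral clustering on a similarity network: normalized-Laplacian
# embedding, k-means with k-means++ seeding, eigengap diagnostics.

# connected components of the graph with edges where W > 0 (off-diagonal)
.graph_components <- function(W) {
  n <- nrow(W)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      i <- queue[[1]]; queue <- queue[-1]
      nb <- which(W[i, ] > 0 & comp == 0L)
      nb <- setdiff(nb, i)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# eigen-decomposition of the symmetric normalized Laplacian
# L = I - D^{-1/2} W D^{-1/2}; returns values ascending and vectors with a
# deterministic sign (largest-magnitude entry positive).
.laplacian_eigen <- function(net) {
  W <- net$matrix
  comp <- .graph_components(W)
  if (max(comp) > 1L)
    stop_idsn("network is disconnected: %d components of sizes %s",
              max(comp), paste(tabulate(comp), collapse = ","))
  dvec <- rowSums(W)
  dinv <- 1 / sqrt(dvec)
  L <- diag(nrow(W)) - (dinv * W) * rep(dinv, each = nrow(W))
  L <- (L + t(L)) / 2
  e <- eigen(L, symmetric = TRUE)
  ord <- rev(seq_along(e$values))       # ascending eigenvalues
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  for (j in seq_len(ncol(vecs))) {
    i0 <- which.max(abs(vecs[, j]))
    if (vecs[i0, j] < 0) vecs[, j] <- -vecs[, j]
  }
  list(values = pmax(vals, 0), vectors = vecs)
}

#' Spectral embedding of a similarity network
#'
#' Rows are the first k eigenvectors of the symmetric normalised Laplacian
#' `L = I - D^(-1/2) W D^(-1/2)`, row-normalised to unit length.
#' Deterministic: eigenvector signs are fixed so the largest-magnitude entry
#' is positive.
#'
#' @param net A connected [similarity_network()] on similarity scale.
#' @param k Number of embedding dimensions.
#' @return n x k matrix with drug ids as rownames; attribute `eigenvalues`
#'   holds the first k+1 Laplacian eigenvalues (non-decreasing).
#' @export
spectral_embedding <- function(net, k) {
  .assert_count(k, "k")
  n <- length(net$ids)
  if (k > n) stop_idsn("k = %d exceeds number of drugs n = %d", k, n)
  e <- .laplacian_eigen(net)
  emb <- e$vectors[, seq_len(k), drop = FALSE]
  nrm <- sqrt(rowSums(emb^2))
  nrm[nrm == 0] <- 1
  emb <- emb / nrm
  rownames(emb) <- net$ids
  attr(emb, "eigenvalues") <- e$values[seq_len(min(k + 1L, n))]
  emb
}

# k-means++ seeding (Arthur & Vassilvitskii) on rows of X
.kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums((X - matrix(X[centers[1], ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) centers[j] <- sample.int(n, 1L)
    else centers[j] <- sample.int(n, 1L, prob = d2 / sum(d2))
    dn <- rowSums((X - matrix(X[centers[j], ], n, ncol(X), byrow = TRUE))^2)
    d2 <- pmin(d2, dn)
  }
  X[centers, , drop = FALSE]
}

#' Spectral clustering
#'
#' Runs k-means (k-means++ initialisation, `restarts` restarts, fixed seed)
#' on the spectral embedding and relabels clusters by descending size
#' (ties by smallest member index) so labels are deterministic.
#'
#' @param net A connected [similarity_network()].
#' @param k Number of clusters (2 <= k <= n).
#' @param seed Integer seed driving the k-means initialisations.
#' @param restarts Number of k-means restarts (best total within-cluster sum
#'   of squares wins), default 10.
#' @return A `clustering_result`: list with `labels` (named integer vector,
#'   clusters 0..k-1), `k`, `embedding`, `eigenvalues`, `seed`.
#' @export
spectral_cluster <- function(net, k, seed = 1L, restarts = 10L) {
  .assert_count(k, "k")
  n <- length(net$ids)
  if (k > n) stop_idsn("k = %d exceeds number of drugs n = %d", k, n)
  emb <- spectral_embedding(net, k)
  if (k == n) {   # degenerate: every drug its own cluster
    res <- list(labels = stats::setNames(seq_len(n) - 1L, net$ids),
                k = as.integer(k), embedding = emb,
                eigenvalues = attr(emb, "eigenvalues"),
                seed = as.integer(seed))
    class(res) <- "clustering_result"
    return(res)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- .kmeanspp_centers(emb, k)
    km <- suppressWarnings(
      stats::kmeans(emb, centers = centers, iter.max = 100L))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  raw <- best$cluster
  # relabel by descending cluster size, ties by first occurrence
  sizes <- tabulate(raw, nbins = k)
  first <- vapply(seq_len(k), function(c)
    if (sizes[c] > 0) min(which(raw == c)) else n + 1L, numeric(1))
  ord <- order(-sizes, first)
  relab <- integer(k); relab[ord] <- seq_len(k) - 1L
  labels <- stats::setNames(relab[raw], net$ids)
  res <- list(labels = labels, k = as.integer(k), embedding = emb,
              eigenvalues = attr(emb, "eigenvalues"),
              seed = as.integer(seed))
  class(res) <- "clustering_result"
  res
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> k=%d n=%d seed=%d sizes=%s\n",
              x$k, length(x$labels), x$seed,
              paste(table(x$labels), collapse = ",")))
  invisible(x)
}

#' Eigengap candidates for the number of clusters
#'
#' Ranks k = 2..kmax by the descending gap `lambda_{k+1} - lambda_k` of the
#' normalised-Laplacian spectrum. A large gap after the k-th eigenvalue
#' signals k well-separated blocks. Provided as guidance only; the default
#' pipeline mirrors a fixed k.
#'
#' @param net A connected [similarity_network()].
#' @param kmax Largest k considered (kmax < n).
#' @return Data frame with columns `k` and `gap`, ordered by descending gap.
#' @export
eigengap_candidates <- function(net, kmax) {
  .assert_count(kmax, "kmax")
  n <- length(net$ids)
  if (kmax >= n) stop_idsn("kmax = %d must be < n = %d", kmax, n)
  if (kmax < 2L) stop_idsn("kmax must be >= 2")
  vals <- .laplacian_eigen(net)$values
  ks <- 2:kmax
  gaps <- vals[ks + 1L] - vals[ks]
  out <- data.frame(k = ks, gap = gaps)
  out[order(-out$gap, out$k), , drop = FALSE]
}
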