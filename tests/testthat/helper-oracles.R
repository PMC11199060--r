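# Independent brute-force oracles. These re-derive the quantities under
# test from first principles and must stay independent of the package's
# code paths.

# Affine-gap global alignment score (Gotoh three-state DP). Gap of length k
# costs open + k * ext (open, ext given as positive costs).
oracle_nw_score <- function(a, b, submat, open, ext) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # ends in aligned pair
  X <- matrix(NEG, n + 1, m + 1)  # ends in gap in b (A consumed)
  Y <- matrix(NEG, n + 1, m + 1)  # ends in gap in a
  M[1, 1] <- 0
  for (i in seq_len(n) + 1) X[i, 1] <- -(open + (i - 1) * ext)
  for (j in seq_len(m) + 1) Y[1, j] <- -(open + (j - 1) * ext)
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      s <- submat[A[i - 1], B[j - 1]]
      M[i, j] <- s + max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      X[i, j] <- max(X[i, j], M[i - 1, j] - open - ext, X[i - 1, j] - ext,
                     Y[i - 1, j] - open - ext)
      Y[i, j] <- max(Y[i, j], M[i, j - 1] - open - ext, Y[i, j - 1] - ext,
                     X[i, j - 1] - open - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Pair-counting adjusted Rand index via the 2x2 pair-agreement table,
# ARI = 2(ad - bc) / ((a+b)(b+d) + (a+c)(c+d)).
oracle_ari <- function(la, lb) {
  n <- length(la)
  a <- b <- c <- d <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- la[i] == la[j]; sb <- lb[i] == lb[j]
    if (sa && sb) a <- a + 1
    else if (sa && !sb) b <- b + 1
    else if (!sa && sb) c <- c + 1
    else d <- d + 1
  }
  denom <- (a + b) * (b + d) + (a + c) * (c + d)
  if (denom == 0) return(1)
  2 * (a * d - b * c) / denom
}

# Naive per-point silhouette from a distance matrix.
oracle_silhouette <- function(d, labels) {
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- sum(d[i, own]) / length(own)
    b <- Inf
    for (cl in unique(labels)) {
      if (cl == labels[i]) next
      mem <- which(labels == cl)
      b <- min(b, sum(d[i, mem]) / length(mem))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

oracle_davies_bouldin <- function(X, labels) {
  cl <- sort(unique(labels)); k <- length(cl)
  cent <- lapply(cl, function(c) colMeans(X[labels == c, , drop = FALSE]))
  sp <- vapply(seq_len(k), function(ci) {
    Xi <- X[labels == cl[ci], , drop = FALSE]
    mean(apply(Xi, 1, function(r) sqrt(sum((r - cent[[ci]])^2))))
  }, numeric(1))
  total <- 0
  for (i in seq_len(k)) {
    worst <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      dij <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      worst <- max(worst, (sp[i] + sp[j]) / dij)
    }
    total <- total + worst
  }
  total / k
}

oracle_calinski_harabasz <- function(X, labels) {
  cl <- sort(unique(labels)); k <- length(cl); n <- nrow(X)
  g <- colMeans(X)
  B <- 0; W <- 0
  for (c in cl) {
    Xi <- X[labels == c, , drop = FALSE]
    ci <- colMeans(Xi)
    B <- B + nrow(Xi) * sum((ci - g)^2)
    W <- W + sum(sweep(Xi, 2, ci)^2)
  }
  (B / W) * (n - k) / (k - 1)
}

# Exhaustive hypergeometric upper tail: enumerate every size-K subset of
# the universe and count those overlapping the set by >= ov.
oracle_hyper_upper <- function(N, set_idx, K, ov) {
  subsets <- utils::combn(N, K)
  hits <- 0
  for (j in seq_len(ncol(subsets)))
    if (length(intersect(subsets[, j], set_idx)) >= ov) hits <- hits + 1
  hits / ncol(subsets)
}

# Planted k-block similarity network with exact within/between values.
planted_block_network <- function(sizes, within = 0.9, between = 0.1,
                                  source = "fused") {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  m <- matrix(between, n, n)
  for (b in seq_along(sizes)) m[lab == b, lab == b] <- within
  diag(m) <- 1
  ids <- sprintf("d%03d", seq_len(n))
  dimnames(m) <- list(ids, ids)
  list(net = similarity_network(m, source = source, scale = "similarity"),
       truth = stats::setNames(lab, ids))
}
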