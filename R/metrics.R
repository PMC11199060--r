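# Clustering validity indices: external (ARI, NMI against an annotation)
# and internal (silhouette on 1 - similarity; Davies-Bouldin and
# Calinski-Harabasz on the spectral embedding).

.match_labellings <- function(a, b) {
  if (is.null(names(a)) || is.null(names(b)))
    stop_idsn("labellings must be named by drug id")
  if (!setequal(names(a), names(b)) || length(a) != length(b))
    stop_idsn("labellings cover different id sets (%d vs %d ids)",
              length(a), length(b))
  b <- b[names(a)]
  list(a = as.integer(factor(a)), b = as.integer(factor(b)))
}

#' Adjusted Rand index
#'
#' Chance-corrected pair-counting agreement between two partitions of the
#' same drugs, computed from the contingency table:
#' `(sum C(n_ij,2) - E) / (max - E)` with
#' `E = sum C(a_i,2) * sum C(b_j,2) / C(n,2)`.
#'
#' @param a,b Named label vectors over the same id set.
#' @return ARI in \[-1, 1\]; 1 for identical partitions, ~0 for independent
#'   ones.
#' @export
adjusted_rand_index <- function(a, b) {
  m <- .match_labellings(a, b)
  tab <- table(m$a, m$b)
  n <- length(m$a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Normalised mutual information
#'
#' `I(a;b) / sqrt(H(a) * H(b))` with natural-log entropies (geometric-mean
#' normalisation; `"arithmetic"` uses `(H(a)+H(b))/2`). Defined as 1 when
#' both labellings are single-cluster, 0 when exactly one is.
#'
#' @param a,b Named label vectors over the same id set.
#' @param normalization `"geometric"` (default) or `"arithmetic"`.
#' @return NMI in \[0, 1\].
#' @export
normalized_mutual_information <- function(a, b,
                                          normalization = c("geometric",
                                                            "arithmetic")) {
  normalization <- match.arg(normalization)
  m <- .match_labellings(a, b)
  n <- length(m$a)
  tab <- table(m$a, m$b) / n
  pa <- rowSums(tab); pb <- colSums(tab)
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / (outer(pa, pb)[nz])))
  denom <- if (normalization == "geometric") sqrt(ha * hb) else (ha + hb) / 2
  max(0, min(1, mi / denom))
}

#' Silhouette score on a similarity network
#'
#' Distance is `1 - similarity`. For each drug, `a` is the mean distance to
#' its own cluster (excluding itself) and `b` the smallest mean distance to
#' another cluster; the score is the mean of `(b - a)/max(a, b)`. Drugs in
#' singleton clusters contribute 0.
#'
#' @param net A [similarity_network()].
#' @param labels Named label vector over the network's ids.
#' @return Mean silhouette width in \[-1, 1\].
#' @export
silhouette_score <- function(net, labels) {
  labels <- labels[net$ids]
  if (anyNA(labels)) stop_idsn("labels do not cover all network ids")
  if (length(unique(labels)) < 2L)
    stop_idsn("silhouette needs at least 2 clusters")
  d <- 1 - net$matrix
  n <- length(labels)
  cl <- unique(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(cl, labels[i]), function(c)
      mean(d[i, labels == c]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Davies-Bouldin index on embedding coordinates
#'
#' Mean over clusters of the worst ratio `(s_i + s_j) / d_ij`, where `s_i`
#' is the mean distance of cluster members to their centroid and `d_ij` the
#' centroid distance. Lower is better. Pairs of clusters with coincident
#' centroids and zero spread contribute 0 (duplicated points), otherwise a
#' coincident-centroid pair is degenerate and yields Inf.
#'
#' @param embedding n x d coordinate matrix with drug ids as rownames.
#' @param labels Named label vector.
#' @return DBI >= 0.
#' @export
davies_bouldin <- function(embedding, labels) {
  labels <- labels[rownames(embedding)]
  if (anyNA(labels)) stop_idsn("labels do not cover all embedding rows")
  cl <- sort(unique(labels))
  k <- length(cl)
  if (k < 2L) stop_idsn("Davies-Bouldin needs at least 2 clusters")
  cent <- t(vapply(cl, function(c)
    colMeans(embedding[labels == c, , drop = FALSE]), numeric(ncol(embedding))))
  spread <- vapply(seq_len(k), function(ci) {
    X <- embedding[labels == cl[ci], , drop = FALSE]
    mean(sqrt(rowSums((X - matrix(cent[ci, ], nrow(X), ncol(X),
                                  byrow = TRUE))^2)))
  }, numeric(1))
  r <- numeric(k)
  for (i in seq_len(k)) {
    ratios <- vapply(setdiff(seq_len(k), i), function(j) {
      dij <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      num <- spread[i] + spread[j]
      if (dij == 0) { if (num == 0) 0 else Inf } else num / dij
    }, numeric(1))
    r[i] <- max(ratios)
  }
  mean(r)
}

#' Calinski-Harabasz score on embedding coordinates
#'
#' Between-cluster dispersion over within-cluster dispersion, scaled by
#' `(n - k)/(k - 1)`. Higher is better.
#'
#' @inheritParams davies_bouldin
#' @return CH >= 0 (Inf when within-cluster dispersion is zero).
#' @export
calinski_harabasz <- function(embedding, labels) {
  labels <- labels[rownames(embedding)]
  if (anyNA(labels)) stop_idsn("labels do not cover all embedding rows")
  cl <- sort(unique(labels))
  k <- length(cl); n <- nrow(embedding)
  if (k < 2L) stop_idsn("Calinski-Harabasz needs at least 2 clusters")
  gmean <- colMeans(embedding)
  B <- 0; W <- 0
  for (c in cl) {
    X <- embedding[labels == c, , drop = FALSE]
    cm <- colMeans(X)
    B <- B + nrow(X) * sum((cm - gmean)^2)
    W <- W + sum((X - matrix(cm, nrow(X), ncol(X), byrow = TRUE))^2)
  }
  if (W == 0) return(Inf)
  (B / W) * (n - k) / (k - 1)
}

#' Full evaluation grid over networks and annotations
#'
#' Clusters every network at the same k and seed, then computes external
#' metrics (ARI, NMI) against every annotation scheme on the drugs the
#' scheme covers, and internal metrics (silhouette, Davies-Bouldin,
#' Calinski-Harabasz) on each network. Schemes covering fewer than 3 drugs
#' are skipped with a warning; coverage is reported per row.
#'
#' @param networks Named list of [similarity_network()] objects sharing one
#'   id set.
#' @param annotations List of `annotation_table` objects.
#' @param k Number of clusters.
#' @param seed Clustering seed.
#' @return Data frame with one row per (network, scheme) plus one internal
#'   row per network (`scheme = ".internal"`); columns `network`, `scheme`,
#'   `coverage`, `ari`, `nmi`, `silhouette`, `davies_bouldin`,
#'   `calinski_harabasz`. Attribute `clusterings` holds the
#'   `clustering_result` per network.
#' @export
benchmark_report <- function(networks, annotations = list(), k = 16L,
                             seed = 1L) {
  if (is.null(names(networks)))
    names(networks) <- vapply(networks, `[[`, character(1), "source")
  ids <- .check_same_ids(networks)
  clus <- lapply(networks, spectral_cluster, k = k, seed = seed)
  rows <- list()
  for (nm in names(networks)) {
    res <- clus[[nm]]
    emb <- res$embedding
    rows[[length(rows) + 1L]] <- data.frame(
      network = nm, scheme = ".internal", coverage = length(ids),
      ari = NA_real_, nmi = NA_real_,
      silhouette = silhouette_score(networks[[nm]], res$labels),
      davies_bouldin = davies_bouldin(emb, res$labels),
      calinski_harabasz = calinski_harabasz(emb, res$labels))
    for (ann in annotations) {
      covered <- intersect(ids, names(ann$mapping))
      if (length(covered) < 3L) {
        warning(sprintf("annotation '%s' covers %d < 3 drugs; skipped",
                        ann$scheme, length(covered)), call. = FALSE)
        next
      }
      truth <- ann$mapping[covered]
      pred <- res$labels[covered]
      rows[[length(rows) + 1L]] <- data.frame(
        network = nm, scheme = ann$scheme, coverage = length(covered),
        ari = adjusted_rand_index(pred, truth),
        nmi = normalized_mutual_information(pred, truth),
        silhouette = NA_real_, davies_bouldin = NA_real_,
        calinski_harabasz = NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "clusterings") <- clus
  out
}
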