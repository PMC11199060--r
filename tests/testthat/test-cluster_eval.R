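# Spectral clustering and validity metrics.

test_that("spectral_embedding separates near-disconnected cliques and is deterministic", {
  m <- matrix(1e-6, 10, 10)
  m[1:5, 1:5] <- 0.9; m[6:10, 6:10] <- 0.9; diag(m) <- 1
  ids <- paste0("d", 1:10); dimnames(m) <- list(ids, ids)
  net <- similarity_network(m, source = "fused")
  emb <- spectral_embedding(net, 2)
  within <- max(dist(emb[1:5, ]), dist(emb[6:10, ]))
  between <- min(as.matrix(dist(emb))[1:5, 6:10])
  expect_lt(within, between)
  expect_identical(emb, spectral_embedding(net, 2))
  ev <- attr(emb, "eigenvalues")
  expect_equal(ev[1], 0, tolerance = 1e-8)
  expect_gt(ev[2], 0)       # connected graph: eigenvalue 0 has multiplicity 1

  # identical similarity everywhere -> all embedding rows equal
  u <- matrix(0.5, 6, 6); diag(u) <- 1
  dimnames(u) <- list(paste0("x", 1:6), paste0("x", 1:6))
  embu <- spectral_embedding(similarity_network(u, source = "fused"), 1)
  expect_lt(max(abs(sweep(embu, 2, embu[1, ]))), 1e-10)

  disc <- diag(4); dimnames(disc) <- list(letters[1:4], letters[1:4])
  expect_error(spectral_embedding(similarity_network(disc, source = "chem"),
                                  2), "disconnected")
})

test_that("spectral_cluster recovers planted partitions for k in 2..4 over a seed panel", {
  for (k in 2:4) {
    pb <- planted_block_network(rep(60 %/% k, k), within = 0.9,
                                between = 0.1)
    for (seed in 1:10) {
      res <- spectral_cluster(pb$net, k, seed = seed)
      expect_equal(adjusted_rand_index(res$labels, pb$truth), 1,
                   info = sprintf("k=%d seed=%d", k, seed))
    }
  }
})

test_that("spectral_cluster is deterministic and relabels by size", {
  pb <- planted_block_network(c(10, 6), within = 0.9, between = 0.1)
  r1 <- spectral_cluster(pb$net, 2, seed = 3)
  r2 <- spectral_cluster(pb$net, 2, seed = 3)
  expect_identical(r1$labels, r2$labels)
  # cluster 0 is the larger one
  expect_equal(sum(r1$labels == 0), 10)
  # k = n: every drug its own cluster
  small <- planted_block_network(c(2, 2), within = .9, between = .1)
  rn <- spectral_cluster(small$net, 4, seed = 1)
  expect_length(unique(rn$labels), 4L)
  expect_error(spectral_cluster(small$net, 5, seed = 1), "exceeds")
})

test_that("eigengap ranks the true k first on block fixtures", {
  pb <- planted_block_network(c(7, 7, 7), within = 0.9, between = 0.05)
  cand <- eigengap_candidates(pb$net, 6)
  expect_equal(cand$k[1], 3)
  # complete uniform graph: no dominant gap but a full ranking is returned
  u <- matrix(0.5, 8, 8); diag(u) <- 1
  dimnames(u) <- list(paste0("x", 1:8), paste0("x", 1:8))
  cu <- eigengap_candidates(similarity_network(u, source = "fused"), 5)
  expect_setequal(cu$k, 2:5)
  expect_equal(nrow(eigengap_candidates(pb$net, 2)), 1L)
})

test_that("ARI matches hand-derived values and the pair-counting oracle", {
  ids <- paste0("d", 1:4)
  a <- stats::setNames(c(0, 0, 1, 1), ids)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, stats::setNames(c(1, 1, 0, 0), ids)), 1)
  expect_equal(adjusted_rand_index(a, stats::setNames(c(0, 1, 0, 1), ids)),
               -0.5)
  expect_error(adjusted_rand_index(a, stats::setNames(1:3, ids[1:3])),
               "id set")

  set.seed(17)
  for (case in 1:200) {
    n <- sample(3:8, 1)
    la <- sample(0:2, n, TRUE); lb <- sample(0:2, n, TRUE)
    ids <- paste0("x", seq_len(n))
    expect_equal(adjusted_rand_index(stats::setNames(la, ids),
                                     stats::setNames(lb, ids)),
                 oracle_ari(la, lb), tolerance = 1e-12)
  }
})

test_that("NMI matches contingency arithmetic and its conventions", {
  ids <- paste0("d", 1:4)
  a <- stats::setNames(c(0, 0, 1, 1), ids)
  expect_equal(normalized_mutual_information(a, a), 1)
  # uniform contingency table -> zero mutual information
  expect_equal(normalized_mutual_information(
    a, stats::setNames(c(0, 1, 0, 1), ids)), 0)
  # both single-cluster -> 1; exactly one single-cluster -> 0
  one <- stats::setNames(rep(0, 4), ids)
  expect_equal(normalized_mutual_information(one, one), 1)
  expect_equal(normalized_mutual_information(one, a), 0)
  # independent balanced labellings of large n are near 0
  set.seed(23)
  n <- 4000; ids2 <- paste0("z", 1:n)
  la <- stats::setNames(sample(0:1, n, TRUE), ids2)
  lb <- stats::setNames(sample(0:1, n, TRUE), ids2)
  expect_lt(normalized_mutual_information(la, lb), 0.01)
})

test_that("ARI and NMI are invariant under label permutation", {
  set.seed(29)
  n <- 40; ids <- paste0("d", seq_len(n))
  la <- stats::setNames(sample(0:3, n, TRUE), ids)
  lb <- stats::setNames(sample(0:3, n, TRUE), ids)
  ari0 <- adjusted_rand_index(la, lb)
  nmi0 <- normalized_mutual_information(la, lb)
  for (r in 1:50) {
    pm <- sample(0:3)
    lb2 <- stats::setNames(pm[lb + 1], ids)
    expect_equal(adjusted_rand_index(la, lb2), ari0, tolerance = 1e-12)
    expect_equal(normalized_mutual_information(la, lb2), nmi0,
                 tolerance = 1e-12)
  }
})

test_that("silhouette matches the brute-force oracle and its edge cases", {
  pb <- planted_block_network(c(6, 6), within = 0.95, between = 0.05)
  expect_gt(silhouette_score(pb$net, pb$truth), 0.5)
  # all pairwise distances equal -> 0
  u <- matrix(0.5, 6, 6); diag(u) <- 1
  ids <- paste0("x", 1:6); dimnames(u) <- list(ids, ids)
  lab <- stats::setNames(rep(1:2, each = 3), ids)
  expect_equal(silhouette_score(similarity_network(u, source = "fused"),
                                lab), 0)
  expect_error(silhouette_score(pb$net,
                                stats::setNames(rep(1, 12), pb$net$ids)),
               "2 clusters")
  # oracle agreement on a random 10-drug network
  set.seed(37)
  m <- matrix(runif(100), 10); m <- (m + t(m)) / 2; diag(m) <- 1
  ids <- paste0("d", 1:10); dimnames(m) <- list(ids, ids)
  net <- similarity_network(m, source = "fused")
  labels <- stats::setNames(sample(1:3, 10, TRUE), ids)
  labels[1:3] <- 1:3   # ensure all clusters present
  expect_equal(silhouette_score(net, labels),
               oracle_silhouette(1 - m, labels), tolerance = 1e-12)
})

test_that("Davies-Bouldin and Calinski-Harabasz match oracles and closed forms", {
  # two tight distant blobs with hand-set coordinates
  X <- rbind(matrix(c(0, 0, 0, .1, .1, 0), 3, 2, byrow = TRUE),
             matrix(c(10, 10, 10, 10.1, 10.1, 10), 3, 2, byrow = TRUE))
  rownames(X) <- paste0("d", 1:6)
  lab <- stats::setNames(rep(1:2, each = 3), rownames(X))
  expect_lt(davies_bouldin(X, lab), 0.05)
  expect_gt(calinski_harabasz(X, lab), 1e4)
  # duplicating every point leaves DBI unchanged
  X2 <- rbind(X, X); rownames(X2) <- paste0("d", 1:12)
  lab2 <- stats::setNames(rep(lab, 2), rownames(X2))
  expect_equal(davies_bouldin(X2, lab2), davies_bouldin(X, lab),
               tolerance = 1e-12)
  # oracle equivalence on random 12-point fixtures
  set.seed(41)
  for (r in 1:5) {
    Y <- matrix(rnorm(24), 12, 2); rownames(Y) <- paste0("p", 1:12)
    ly <- stats::setNames(c(1, 2, 3, sample(1:3, 9, TRUE)), rownames(Y))
    expect_equal(davies_bouldin(Y, ly), oracle_davies_bouldin(Y, ly),
                 tolerance = 1e-10)
    expect_equal(calinski_harabasz(Y, ly), oracle_calinski_harabasz(Y, ly),
                 tolerance = 1e-10)
  }
  expect_error(davies_bouldin(X, stats::setNames(rep(1, 6), rownames(X))),
               "2 clusters")
})

test_that("benchmark_report produces the full metric grid", {
  pb <- planted_block_network(c(8, 8), within = 0.9, between = 0.1)
  ann_perfect <- annotation_table("truth",
                                  stats::setNames(paste0("c", pb$truth),
                                                  names(pb$truth)))
  ann_small <- annotation_table("tiny", stats::setNames("A", "d001"))
  expect_warning(
    rep <- benchmark_report(list(planted = pb$net),
                            list(ann_perfect, ann_small), k = 2, seed = 1),
    "tiny")
  expect_equal(nrow(rep), 2L)    # one internal + one external row
  ext <- rep[rep$scheme == "truth", ]
  expect_equal(ext$ari, 1)
  expect_equal(ext$nmi, 1)
  expect_false(anyNA(rep[rep$scheme == ".internal",
                         c("silhouette", "davies_bouldin",
                           "calinski_harabasz")]))
})
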