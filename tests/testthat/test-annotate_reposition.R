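# Edge attribution, contribution report, pair consistency, permutation
# test, candidates, enrichment.

# tiny three-network fixture with controllable entries
make_three_nets <- function(n = 6, seed = 1) {
  set.seed(seed)
  mk <- function(source) {
    m <- matrix(runif(n * n), n); m <- (m + t(m)) / 2; diag(m) <- 1
    ids <- paste0("d", seq_len(n)); dimnames(m) <- list(ids, ids)
    similarity_network(m, source = source)
  }
  list(fused = mk("fused"), chem = mk("chem"), pharm = mk("pharm"))
}

test_that("edge_source_attribution applies the rank rule", {
  ids <- paste0("d", 1:4)
  base <- function(vals) {
    m <- matrix(0, 4, 4, dimnames = list(ids, ids))
    m[upper.tri(m)] <- vals
    m <- m + t(m); diag(m) <- 1
    m
  }
  # 6 upper-tri entries; ranks are (rank-1)/5
  chem <- similarity_network(base(c(.9, .1, .2, .3, .4, .5)), source = "chem")
  pharm <- similarity_network(base(c(.1, .9, .2, .3, .4, .5)), source = "pharm")
  fused <- similarity_network(base(c(.5, .5, .9, .1, .2, .3)), source = "fused")
  labels <- stats::setNames(rep(0L, 4), ids)
  att <- edge_source_attribution(fused, chem, pharm, labels, margin = 0.05)
  expect_equal(nrow(att), 6L)
  expect_true(all(table(paste(att$drug_i, att$drug_j)) == 1))
  get_cat <- function(i, j)
    att$category[att$drug_i == i & att$drug_j == j]
  # pair (d1,d2): chem rank 1.0 dominates -> chemical_structure
  expect_equal(get_cat("d1", "d2"), "chemical_structure")
  # pair (d1,d3): pharm rank 1.0 dominates -> drug_targets
  expect_equal(get_cat("d1", "d3"), "drug_targets")
  # pair (d1,d4): fused rank 1.0 vs both views 0.2 -> fusion_value
  expect_equal(get_cat("d1", "d4"), "fusion_value")
  # equal chem and pharm ranks below fused -> fusion_value by tie rule
  expect_equal(get_cat("d2", "d3"), "fusion_value")
})

test_that("contribution report conserves percentages and flags degenerate clusters", {
  nets <- make_three_nets()
  labels <- stats::setNames(rep(c(0L, 1L), each = 3), nets$fused$ids)
  att <- edge_source_attribution(nets$fused, nets$chem, nets$pharm, labels)
  rep <- cluster_contribution_report(att, labels)
  sums <- rowSums(rep$per_cluster[, c("pct_chemical_structure",
                                      "pct_drug_targets",
                                      "pct_fusion_value")])
  expect_equal(unname(sums), rep(100, 2), tolerance = 1e-9)
  expect_equal(sum(rep$global), 100, tolerance = 1e-9)

  # all-pharm degenerate attribution: 100% drug_targets, entirely determined
  att_pharm <- att
  att_pharm$category <- "drug_targets"
  rep2 <- cluster_contribution_report(att_pharm, labels)
  expect_true(all(rep2$per_cluster$pct_drug_targets == 100))
  expect_true(all(rep2$per_cluster$entirely_determined))
  expect_true(all(rep2$per_cluster$dominant_category == "drug_targets"))
  # 3 chem + 1 pharm -> 75/25/0
  att4 <- att[att$cluster == 0, ][1:4, ]
  att4$category <- c("chemical_structure", "chemical_structure",
                     "chemical_structure", "drug_targets")
  att4$cluster <- 0L
  rep3 <- cluster_contribution_report(att4, labels[labels == 0])
  expect_equal(rep3$per_cluster$pct_chemical_structure, 75)
  expect_equal(rep3$per_cluster$pct_drug_targets, 25)
  expect_equal(rep3$per_cluster$pct_fusion_value, 0)
  # singleton cluster reported with no edges
  lab1 <- c(labels, stats::setNames(2L, "lonely"))
  rep4 <- cluster_contribution_report(att, lab1)
  expect_equal(rep4$per_cluster$n_edges[rep4$per_cluster$cluster == 2], 0L)
})

test_that("top_similar_pairs ranks deterministically with lexicographic ties", {
  ids <- c("a", "b", "c")
  m <- matrix(c(1, .9, .3, .9, 1, .9, .3, .9, 1), 3, 3,
              dimnames = list(ids, ids))
  net <- similarity_network(m, source = "fused")
  top1 <- top_similar_pairs(net, 1)
  expect_identical(top1$drug_i, "a")   # (a,b) beats (b,c) on tie
  expect_identical(top1$drug_j, "b")
  full <- top_similar_pairs(net, 3)
  expect_identical(full$drug_i, c("a", "b", "a"))
  expect_identical(full$similarity, c(.9, .9, .3))
  expect_identical(top_similar_pairs(net, 3), full)   # stable across runs
  expect_error(top_similar_pairs(net, 4), "exceeds")
})

test_that("pathway_consistency counts fractions and dropped pairs", {
  pairs <- data.frame(rank = 1:4,
                      drug_i = c("a", "a", "b", "c"),
                      drug_j = c("b", "c", "c", "d"),
                      similarity = c(.9, .8, .7, .6))
  class(pairs) <- c("pair_report", "data.frame")
  annot <- annotation_table("pathway",
                            c(a = "P1", b = "P1", c = "P1", d = "P2"))
  pc <- pathway_consistency(pairs, annot)
  expect_equal(pc$fraction, 0.75)   # 3 of 4 consistent
  expect_equal(pc$n_dropped, 0L)
  # consistency invariant to swapping pair orientation
  pairs2 <- pairs
  pairs2$drug_i <- pairs$drug_j; pairs2$drug_j <- pairs$drug_i
  expect_equal(pathway_consistency(pairs2, annot)$fraction, 0.75)
  # unannotated drug -> pair dropped and counted
  annot2 <- annotation_table("pathway", c(a = "P1", b = "P1", c = "P1"))
  pc2 <- pathway_consistency(pairs, annot2)
  expect_equal(pc2$n_dropped, 1L)
  expect_equal(pc2$fraction, 1)
  annot3 <- annotation_table("pathway", c(x = "P1"))
  expect_error(pathway_consistency(pairs, annot3), "annotated")
})

test_that("repositioning_candidates uses a strict threshold on inconsistent pairs", {
  ids <- c("a", "b", "c", "d")
  m <- matrix(0.2, 4, 4, dimnames = list(ids, ids))
  m["a", "b"] <- m["b", "a"] <- 0.8    # inconsistent pair above threshold
  m["c", "d"] <- m["d", "c"] <- 0.69   # inconsistent pair below
  m["a", "c"] <- m["c", "a"] <- 0.9    # consistent pair above
  diag(m) <- 1
  net <- similarity_network(m, source = "fused")
  annot <- annotation_table("pathway",
                            c(a = "P1", b = "P2", c = "P1", d = "P3"))
  cand <- repositioning_candidates(net, annot, 0.7)
  expect_equal(nrow(cand), 1L)
  expect_identical(cand$drug_i, "a"); expect_identical(cand$drug_j, "b")
  expect_identical(cand$pathway_j, "P2")
  # all consistent -> empty
  same <- annotation_table("pathway",
                           c(a = "P1", b = "P1", c = "P1", d = "P1"))
  expect_equal(nrow(repositioning_candidates(net, same, 0.7)), 0L)
  # boundary: 0.7 itself is excluded
  m2 <- m; m2["a", "b"] <- m2["b", "a"] <- 0.7
  net2 <- similarity_network(m2, source = "fused")
  annot_ab <- annotation_table("pathway",
                               c(a = "P1", b = "P2", c = "P1", d = "P1"))
  expect_equal(nrow(repositioning_candidates(net2, annot_ab, 0.7)), 0L)
  expect_error(repositioning_candidates(net, annot, 1.2), "0,1")
})

test_that("cluster_consistency_pvalue is seeded, bounded, and sane", {
  pb <- planted_block_network(c(8, 8), within = 0.9, between = 0.1)
  annot <- annotation_table("pathway",
                            stats::setNames(paste0("P", pb$truth),
                                            names(pb$truth)))
  res1 <- cluster_consistency_pvalue(pb$truth, pb$net, annot,
                                     top_n = 30, n_perm = 199, seed = 5)
  res2 <- cluster_consistency_pvalue(pb$truth, pb$net, annot,
                                     top_n = 30, n_perm = 199, seed = 5)
  expect_identical(res1, res2)
  expect_true(all(res1$p >= 1 / 200 & res1$p <= 1, na.rm = TRUE))
  # perfectly consistent clusters against a permuted null: small p,
  # bounded below by the add-one rule
  expect_true(all(res1$observed == 1, na.rm = TRUE))
  expect_error(cluster_consistency_pvalue(pb$truth, pb$net, annot,
                                          n_perm = 50), "100")
})

test_that("hypergeometric enrichment matches closed form and enumeration", {
  universe <- paste0("g", 1:10)
  sets <- list(hit = paste0("g", 1:5))
  clusters <- list(cl1 = paste0("g", c(1, 2, 3, 4)))
  rows <- hypergeometric_enrichment(clusters, sets, universe)
  expect_equal(rows$p, 5 / 210, tolerance = 1e-12)   # C(5,4)C(5,0)/C(10,4)
  expect_equal(rows$overlap, 4L)

  # overlap 0 with a tiny set: upper tail including observed -> p = 1
  rows0 <- hypergeometric_enrichment(list(cl = "g6"), list(s = "g1"),
                                     universe)
  expect_equal(rows0$p, 1)

  # exhaustive enumeration oracle for universes <= 12
  set.seed(43)
  for (r in 1:10) {
    N <- sample(6:12, 1)
    uni <- paste0("u", seq_len(N))
    set_idx <- sample(N, sample(2:(N - 1), 1))
    K <- sample(2:(N - 1), 1)
    draw <- sample(uni, K)
    rows <- hypergeometric_enrichment(list(c1 = draw),
                                      list(s = uni[set_idx]), uni)
    expect_equal(rows$p, oracle_hyper_upper(N, set_idx, K, rows$overlap),
                 tolerance = 1e-12)
  }
  expect_error(hypergeometric_enrichment(list(), list(), character(0)),
               "empty universe")
})

test_that("BH q-values are monotone after the step-up and rows sorted by q", {
  set.seed(47)
  uni <- paste0("g", 1:40)
  sets <- lapply(1:6, function(i) sample(uni, 8))
  names(sets) <- paste0("s", 1:6)
  clusters <- lapply(1:4, function(i) sample(uni, 10))
  names(clusters) <- paste0("c", 1:4)
  rows <- hypergeometric_enrichment(clusters, sets, uni)
  expect_true(!is.unsorted(rows$q))
  byp <- rows[order(rows$p), ]
  expect_true(all(byp$q >= byp$p - 1e-12))
  expect_equal(rows$q, stats::p.adjust(rows$p, "BH"), tolerance = 1e-12)
})

test_that("cluster_target_sets collects unique target ids per cluster", {
  prof <- list(
    d1 = list(drug_id = "d1", targets = list(list(target_id = "t1",
                                                  sequence = "MK"),
                                             list(target_id = "t2",
                                                  sequence = "MK"))),
    d2 = list(drug_id = "d2", targets = list(list(target_id = "t1",
                                                  sequence = "MK"))))
  class(prof) <- "drug_cohort"
  labels <- c(d1 = 1L, d2 = 1L)
  sets <- cluster_target_sets(prof, labels)
  expect_identical(sets[["1"]], c("t1", "t2"))
})
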