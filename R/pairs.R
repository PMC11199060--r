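# Repositioning analyses on the fused network: top similar pairs, pathway
# consistency, per-cluster permutation significance, candidate pairs.

#' Top-n most similar drug pairs
#'
#' All unordered off-diagonal pairs ranked by descending similarity; ties
#' are broken lexicographically by (drug_i, drug_j), so the ranking is
#' stable across runs and platforms.
#'
#' @param net A [similarity_network()].
#' @param n Number of pairs to return (<= n_drugs*(n_drugs-1)/2).
#' @return Data frame (class `pair_report`): `rank`, `drug_i`, `drug_j`
#'   (with `drug_i < drug_j`), `similarity`.
#' @export
top_similar_pairs <- function(net, n) {
  .assert_count(n, "n")
  nd <- length(net$ids)
  npairs <- nd * (nd - 1) / 2
  if (n > npairs)
    stop_idsn("n = %d exceeds number of unordered pairs %d", n, npairs)
  ut <- which(upper.tri(net$matrix), arr.ind = TRUE)
  i1 <- pmin(net$ids[ut[, 1]], net$ids[ut[, 2]])
  i2 <- pmax(net$ids[ut[, 1]], net$ids[ut[, 2]])
  df <- data.frame(drug_i = i1, drug_j = i2,
                   similarity = net$matrix[ut])
  df <- df[order(-df$similarity, df$drug_i, df$drug_j), , drop = FALSE]
  df <- df[seq_len(n), , drop = FALSE]
  df <- cbind(rank = seq_len(n), df)
  rownames(df) <- NULL
  class(df) <- c("pair_report", "data.frame")
  df
}

#' Pathway consistency of a pair list
#'
#' Annotates each pair with both drugs' pathway labels and a `consistent`
#' flag (identical labels); pairs where either drug is unannotated are
#' dropped and counted. The headline number is the consistent fraction
#' among annotated pairs.
#'
#' @param pairs A `pair_report` from [top_similar_pairs()].
#' @param annot An `annotation_table` (scheme typically `"pathway"`).
#' @return List with `fraction` (consistent fraction), `pairs` (annotated
#'   pair report with `pathway_i`, `pathway_j`, `consistent`), `n_dropped`
#'   (pairs lost to missing annotation).
#' @export
pathway_consistency <- function(pairs, annot) {
  pi <- unname(annot$mapping[pairs$drug_i])
  pj <- unname(annot$mapping[pairs$drug_j])
  keep <- !is.na(pi) & !is.na(pj)
  n_dropped <- sum(!keep)
  if (!any(keep)) stop_idsn("no pair has both drugs annotated in scheme '%s'",
                            annot$scheme)
  out <- pairs[keep, , drop = FALSE]
  out$pathway_i <- pi[keep]
  out$pathway_j <- pj[keep]
  out$consistent <- out$pathway_i == out$pathway_j
  rownames(out) <- NULL
  list(fraction = mean(out$consistent), pairs = out, n_dropped = n_dropped)
}

#' Per-cluster pathway-consistency permutation test
#'
#' For each cluster, the observed statistic is the consistent fraction among
#' the cluster's pairs that appear in the global top-`top_n` list. The null
#' redistributes pathway labels by `n_perm` seeded random permutations of
#' the annotation across drugs; `p = (1 + #[null >= observed]) / (1 +
#' n_perm)` (add-one permutation p-value, bounded below by `1/(n_perm+1)`).
#' Clusters with no top-n pairs get `p = NA`.
#'
#' @param labels Named cluster labels.
#' @param net Fused [similarity_network()].
#' @param annot Pathway `annotation_table` covering the network ids.
#' @param top_n Size of the global top-pair list (default 100).
#' @param n_perm Number of permutations (>= 100; default 999).
#' @param seed Integer seed for the permutations.
#' @return Data frame: `cluster`, `n_pairs` (cluster pairs in the top list),
#'   `observed` (consistent fraction), `p`, `neg_log10_p`.
#' @export
cluster_consistency_pvalue <- function(labels, net, annot, top_n = 100L,
                                       n_perm = 999L, seed = 1L) {
  if (n_perm < 100L) stop_idsn("n_perm must be >= 100")
  top <- top_similar_pairs(net, min(top_n, length(net$ids) *
                                      (length(net$ids) - 1) / 2))
  labels <- labels[net$ids]
  pair_cl <- ifelse(labels[top$drug_i] == labels[top$drug_j],
                    labels[top$drug_i], NA_integer_)
  ann_ids <- intersect(net$ids, names(annot$mapping))
  obs_lab <- annot$mapping[ann_ids]
  consistent_frac <- function(mapping) {
    pi <- mapping[top$drug_i]; pj <- mapping[top$drug_j]
    ok <- !is.na(pi) & !is.na(pj)
    vapply(sort(unique(labels)), function(cl) {
      sel <- ok & !is.na(pair_cl) & pair_cl == cl
      if (!any(sel)) return(NA_real_)
      mean(pi[sel] == pj[sel])
    }, numeric(1))
  }
  observed <- consistent_frac(stats::setNames(obs_lab, ann_ids))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  clusters <- sort(unique(labels))
  exceed <- integer(length(clusters))
  valid <- !is.na(observed)
  for (b in seq_len(n_perm)) {
    perm <- stats::setNames(sample(obs_lab), ann_ids)
    nullf <- consistent_frac(perm)
    exceed <- exceed + as.integer(valid & !is.na(nullf) & nullf >= observed)
  }
  p <- ifelse(valid, (1 + exceed) / (1 + n_perm), NA_real_)
  n_pairs <- vapply(clusters, function(cl)
    sum(!is.na(pair_cl) & pair_cl == cl), integer(1))
  data.frame(cluster = clusters, n_pairs = n_pairs, observed = observed,
             p = p, neg_log10_p = -log10(p))
}

#' Drug repositioning candidates
#'
#' All unordered annotated pairs with fused similarity strictly greater
#' than `sim_threshold` whose pathway labels differ: a drug highly similar
#' to drugs of another pathway is a repositioning lead, and the partner's
#' pathway is its suggested potential pathway.
#'
#' @param net Fused [similarity_network()].
#' @param annot Pathway `annotation_table`.
#' @param sim_threshold Similarity cutoff in (0, 1); strict `>` (default
#'   0.7).
#' @return Data frame sorted by descending similarity: `drug_i`, `drug_j`,
#'   `similarity`, `pathway_i`, `pathway_j`.
#' @export
repositioning_candidates <- function(net, annot, sim_threshold = 0.7) {
  if (sim_threshold <= 0 || sim_threshold >= 1)
    stop_idsn("sim_threshold must be in (0,1)")
  ut <- which(upper.tri(net$matrix), arr.ind = TRUE)
  i1 <- pmin(net$ids[ut[, 1]], net$ids[ut[, 2]])
  i2 <- pmax(net$ids[ut[, 1]], net$ids[ut[, 2]])
  s <- net$matrix[ut]
  pi <- unname(annot$mapping[i1]); pj <- unname(annot$mapping[i2])
  keep <- s > sim_threshold & !is.na(pi) & !is.na(pj) & pi != pj
  out <- data.frame(drug_i = i1[keep], drug_j = i2[keep],
                    similarity = s[keep], pathway_i = pi[keep],
                    pathway_j = pj[keep])
  out <- out[order(-out$similarity, out$drug_i, out$drug_j), , drop = FALSE]
  rownames(out) <- NULL
  out
}
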