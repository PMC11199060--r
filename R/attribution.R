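# Which data view explains each within-cluster edge of the fused network?
# Chem, pharm and fused matrices live on different scales after SNF, so
# edges are compared on rank-transformed similarities.

# rank-transform the off-diagonal entries of a symmetric matrix to [0,1]
# (average ranks for ties); returns a matrix with NA diagonal.
.rank_transform <- function(m) {
  n <- nrow(m)
  ut <- upper.tri(m)
  vals <- m[ut]
  if (length(vals) == 1L) rk <- 0.5
  else rk <- (rank(vals, ties.method = "average") - 1) / (length(vals) - 1)
  out <- matrix(NA_real_, n, n, dimnames = dimnames(m))
  out[ut] <- rk
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  out
}

#' Attribute within-cluster fused edges to their source data type
#'
#' For every unordered drug pair inside a cluster, each network's
#' off-diagonal entries are rank-transformed to \[0, 1\] and the pair is
#' categorised: if the fused rank exceeds both single-view ranks by more
#' than `margin`, the edge is a `fusion_value` edge (the fusion itself made
#' it strong); otherwise the view with the larger rank wins
#' (`chemical_structure` or `drug_targets`), with exact chem/pharm ties
#' going to `fusion_value`.
#'
#' @param fused,chem,pharm [similarity_network()] objects on one id set.
#' @param labels Named cluster labels over the same ids.
#' @param margin Rank margin above the best single view required to call a
#'   fusion edge (default 0.05).
#' @return Data frame (class `edge_attribution`) with one row per
#'   within-cluster pair: `cluster`, `drug_i`, `drug_j`, `chem_s`,
#'   `pharm_s`, `fused_s`, `chem_rank`, `pharm_rank`, `fused_rank`,
#'   `category`.
#' @export
edge_source_attribution <- function(fused, chem, pharm, labels,
                                    margin = 0.05) {
  ids <- .check_same_ids(list(fused, chem, pharm))
  labels <- labels[ids]
  if (anyNA(labels)) stop_idsn("labels do not cover all network ids")
  rf <- .rank_transform(fused$matrix)
  rc <- .rank_transform(chem$matrix)
  rp <- .rank_transform(pharm$matrix)
  rows <- list()
  for (cl in sort(unique(labels))) {
    members <- ids[labels == cl]
    if (length(members) < 2L) next
    for (a in seq_len(length(members) - 1L))
      for (b in (a + 1L):length(members)) {
        i <- members[a]; j <- members[b]
        crk <- rc[i, j]; prk <- rp[i, j]; frk <- rf[i, j]
        category <- if (frk > max(crk, prk) + margin) "fusion_value"
          else if (crk > prk) "chemical_structure"
          else if (prk > crk) "drug_targets"
          else "fusion_value"   # exact chem/pharm tie
        rows[[length(rows) + 1L]] <- data.frame(
          cluster = cl, drug_i = i, drug_j = j,
          chem_s = chem$matrix[i, j], pharm_s = pharm$matrix[i, j],
          fused_s = fused$matrix[i, j],
          chem_rank = crk, pharm_rank = prk, fused_rank = frk,
          category = category)
      }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(0), drug_i = character(0),
               drug_j = character(0), chem_s = numeric(0),
               pharm_s = numeric(0), fused_s = numeric(0),
               chem_rank = numeric(0), pharm_rank = numeric(0),
               fused_rank = numeric(0), category = character(0))
  class(out) <- c("edge_attribution", "data.frame")
  out
}

#' Per-cluster data-type contribution report
#'
#' Percentages of within-cluster edges per category (`chemical_structure`,
#' `drug_targets`, `fusion_value`); clusters where one category exceeds
#' `flag_threshold` percent are flagged `dominant`, clusters with a single
#' category at 100% are flagged `entirely_determined`. Size-1 clusters have
#' no edges: they appear with `n_edges = 0` and NA percentages and are
#' excluded from the global percentages.
#'
#' @param attribution An `edge_attribution` from
#'   [edge_source_attribution()].
#' @param labels Named cluster labels (supplies clusters with no edges).
#' @param flag_threshold Dominance threshold in percent, default 70.
#' @return List with `per_cluster` (data frame: cluster, n_edges, percent
#'   per category, dominant_category, entirely_determined) and `global`
#'   (named percentage vector summing to 100).
#' @export
cluster_contribution_report <- function(attribution, labels,
                                        flag_threshold = 70) {
  cats <- c("chemical_structure", "drug_targets", "fusion_value")
  clusters <- sort(unique(labels))
  rows <- list()
  for (cl in clusters) {
    sub <- attribution[attribution$cluster == cl, , drop = FALSE]
    ne <- nrow(sub)
    if (ne == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, n_edges = 0L,
        pct_chemical_structure = NA_real_, pct_drug_targets = NA_real_,
        pct_fusion_value = NA_real_, dominant_category = NA_character_,
        entirely_determined = NA)
      next
    }
    pct <- 100 * vapply(cats, function(c) sum(sub$category == c),
                        numeric(1)) / ne
    dom <- if (max(pct) > flag_threshold) cats[which.max(pct)] else
      NA_character_
    rows[[length(rows) + 1L]] <- data.frame(
      cluster = cl, n_edges = ne,
      pct_chemical_structure = pct[[1]], pct_drug_targets = pct[[2]],
      pct_fusion_value = pct[[3]], dominant_category = dom,
      entirely_determined = max(pct) == 100)
  }
  per_cluster <- do.call(rbind, rows)
  if (nrow(attribution)) {
    glob <- 100 * vapply(cats, function(c) sum(attribution$category == c),
                         numeric(1)) / nrow(attribution)
  } else glob <- stats::setNames(rep(NA_real_, 3), cats)
  names(glob) <- cats
  list(per_cluster = per_cluster, global = glob)
}
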