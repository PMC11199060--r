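# Hypergeometric over-representation of cluster target sets in user-supplied
# gene-set collections (GMT), with Benjamini-Hochberg adjustment.

#' Hypergeometric gene-set enrichment per cluster
#'
#' For each (cluster, gene set) pair, tests whether the cluster's target ids
#' are over-represented in the set with an upper-tail hypergeometric test
#' including the observed overlap: `p = P(X >= overlap)` for X
#' hypergeometric(set size, universe - set size, cluster size). Gene sets
#' are intersected with the universe first; BH adjustment is applied across
#' all rows.
#'
#' @param cluster_targets Named list: cluster id -> character vector of
#'   target ids (each a subset of `universe`).
#' @param gene_sets Named list of character vectors (see [read_gmt()]).
#' @param universe Character vector of all target ids under consideration
#'   (defaults to the union of all cluster target sets).
#' @return Data frame sorted by ascending q then p: `cluster`, `gene_set`,
#'   `overlap`, `cluster_size`, `set_size`, `universe_size`, `p`, `q`.
#' @export
hypergeometric_enrichment <- function(cluster_targets, gene_sets,
                                      universe = NULL) {
  if (is.null(universe)) universe <- unique(unlist(cluster_targets))
  universe <- unique(universe)
  if (length(universe) == 0L) stop_idsn("empty universe")
  for (nm in names(cluster_targets)) {
    extra <- setdiff(cluster_targets[[nm]], universe)
    if (length(extra))
      stop_idsn("cluster %s has target(s) outside the universe: %s", nm,
                paste(extra, collapse = ","))
  }
  N <- length(universe)
  rows <- list()
  for (cl in names(cluster_targets)) {
    draw <- unique(cluster_targets[[cl]])
    for (gs in names(gene_sets)) {
      set <- intersect(unique(gene_sets[[gs]]), universe)
      m <- length(set)
      ov <- length(intersect(draw, set))
      # upper tail including the observed count
      p <- stats::phyper(ov - 1L, m, N - m, length(draw),
                         lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, gene_set = gs, overlap = ov,
        cluster_size = length(draw), set_size = m, universe_size = N,
        p = p)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$q, out$p, out$cluster, out$gene_set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collect per-cluster target-id sets from a cohort
#'
#' @param profiles A `drug_cohort`.
#' @param labels Named cluster labels over (a subset of) the cohort.
#' @return Named list cluster -> unique target ids of its member drugs.
#' @export
cluster_target_sets <- function(profiles, labels) {
  out <- list()
  for (cl in sort(unique(labels))) {
    members <- names(labels)[labels == cl]
    tg <- unlist(lapply(profiles[members], function(p)
      vapply(p$targets, `[[`, character(1), "target_id")))
    out[[as.character(cl)]] <- unique(unname(tg))
  }
  out
}
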