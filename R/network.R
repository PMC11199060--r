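#' Similarity network container
#'
#' A `similarity_network` holds a symmetric non-negative drug-by-drug matrix
#' together with the ordered drug identifiers that index its rows and
#' columns, a `source` tag saying which data view produced it, and the scale
#' it lives on (`"similarity"`: entries in \[0, 1\]; `"affinity"`:
#' non-negative reals, e.g. SNF kernel output).
#'
#' @param matrix Numeric n x n matrix, symmetric to 1e-10, no negative
#'   entries.
#' @param ids Character vector of n unique drug ids (defaults to the matrix
#'   dimnames).
#' @param source One of `"chem"`, `"pharm"`, `"fused"`.
#' @param scale One of `"similarity"`, `"affinity"`.
#' @param meta Optional named list of metadata (seed, config hash,
#'   diagnostics); carried through and written to file headers.
#' @return An object of class `similarity_network` with elements `ids`,
#'   `matrix`, `source`, `scale`, `meta`.
#' @export
similarity_network <- function(matrix, ids = rownames(matrix),
                               source = c("chem", "pharm", "fused"),
                               scale = c("similarity", "affinity"),
                               meta = list()) {
  source <- match.arg(source)
  scale <- match.arg(scale)
  if (!is.matrix(matrix) || !is.numeric(matrix) || nrow(matrix) != ncol(matrix))
    stop_idsn("'matrix' must be a square numeric matrix")
  n <- nrow(matrix)
  if (is.null(ids)) stop_idsn("drug ids are required (none given, no dimnames)")
  ids <- as.character(ids)
  if (length(ids) != n) stop_idsn("length(ids) != nrow(matrix)")
  if (anyDuplicated(ids))
    stop_idsn("duplicate drug id(s): %s",
              paste(unique(ids[duplicated(ids)]), collapse = ","))
  if (any(!is.finite(matrix))) stop_idsn("matrix contains non-finite entries")
  asym <- max(abs(matrix - t(matrix)))
  if (asym > 1e-10)
    stop_idsn("matrix is not symmetric: max |Mij - Mji| = %g", asym)
  if (any(matrix < 0))
    stop_idsn("matrix has negative entries (min = %g)", min(matrix))
  if (scale == "similarity" && any(matrix > 1 + 1e-10))
    stop_idsn("similarity-scale matrix has entries > 1 (max = %g)", max(matrix))
  m <- (matrix + t(matrix)) / 2   # exact symmetry for downstream eigensolvers
  dimnames(m) <- list(ids, ids)
  structure(list(ids = ids, matrix = m, source = source, scale = scale,
                 meta = meta),
            class = "similarity_network")
}

#' @export
print.similarity_network <- function(x, ...) {
  cat(sprintf("<similarity_network> source=%s scale=%s n=%d drugs\n",
              x$source, x$scale, length(x$ids)))
  off <- x$matrix[upper.tri(x$matrix)]
  if (length(off))
    cat(sprintf("  off-diagonal: min=%.4g mean=%.4g max=%.4g\n",
                min(off), mean(off), max(off)))
  invisible(x)
}

# Check that a list of networks shares one id set in one order; error lists
# the offending ids.
.check_same_ids <- function(nets) {
  ids <- nets[[1]]$ids
  for (k in seq_along(nets)[-1]) {
    if (!identical(nets[[k]]$ids, ids)) {
      diff <- union(setdiff(ids, nets[[k]]$ids), setdiff(nets[[k]]$ids, ids))
      if (length(diff) == 0) diff <- "(same set, different order)"
      stop_idsn("networks disagree on drug ids: %s",
                paste(diff, collapse = ","))
    }
  }
  ids
}

#' Reorder (permute) a similarity network
#'
#' @param net A [similarity_network()].
#' @param ids Character vector: a permutation of `net$ids`.
#' @return The permuted network.
#' @export
permute_network <- function(net, ids) {
  if (!setequal(ids, net$ids) || length(ids) != length(net$ids))
    stop_idsn("'ids' must be a permutation of the network's ids")
  idx <- match(ids, net$ids)
  similarity_network(net$matrix[idx, idx, drop = FALSE], ids = ids,
                     source = net$source, scale = net$scale, meta = net$meta)
}
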