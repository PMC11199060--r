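# Construction of the two single-property drug similarity networks.

#' Build the chemical-structure DSN
#'
#' Pairwise fingerprint similarity (cosine by default, Tanimoto optional)
#' over all drugs, diagonal set to 1, ids in profile order.
#'
#' @param profiles A fingerprinted `drug_cohort` (see
#'   [fingerprint_cohort()]).
#' @param metric `"cosine"` or `"tanimoto"`.
#' @param meta Metadata list stored on the network (seed, config hash).
#' @return A [similarity_network()] with `source = "chem"`.
#' @export
build_chem_dsn <- function(profiles, metric = c("cosine", "tanimoto"),
                           meta = list()) {
  metric <- match.arg(metric)
  ids <- names(profiles)
  fps <- lapply(profiles, function(p) {
    if (is.null(p$fingerprint))
      stop_idsn("drug %s has no fingerprint; run fingerprint_cohort() first",
                p$drug_id)
    p$fingerprint$bits
  })
  n <- length(ids)
  B <- do.call(rbind, fps)              # n x L
  if (metric == "cosine") {
    norms <- sqrt(rowSums(B^2))
    zero <- which(norms == 0)
    if (length(zero))
      stop_idsn("zero fingerprint vector for drug %s", ids[zero[[1]]])
    m <- (B %*% t(B)) / outer(norms, norms)
  } else {
    inter <- B %*% t(B)
    card <- rowSums(B)
    uni <- outer(card, card, "+") - inter
    m <- inter / uni
  }
  m <- pmin(m, 1)
  diag(m) <- 1
  similarity_network((m + t(m)) / 2, ids = ids, source = "chem",
                     scale = "similarity", meta = meta)
}

#' Build the pharmacological (target-sequence) DSN
#'
#' All-pairs drug similarity from normalised protein alignment scores of the
#' drugs' targets. Drugs without targets must be excluded beforehand (see
#' [drugs_with_targets()]); alignment scores between identical sequences are
#' computed once (sequences are deduplicated internally).
#'
#' @param profiles A `drug_cohort`, every profile with >= 1 target.
#' @param scoring An [alignment_scoring()].
#' @param aggregator `"max"` or `"mean"` over target cross-pairs.
#' @param meta Metadata list stored on the network.
#' @return A [similarity_network()] with `source = "pharm"`.
#' @export
build_pharm_dsn <- function(profiles, scoring = alignment_scoring(),
                            aggregator = c("max", "mean"), meta = list()) {
  aggregator <- match.arg(aggregator)
  ids <- names(profiles)
  n_targets <- vapply(profiles, function(p) length(p$targets), integer(1))
  if (any(n_targets == 0L))
    stop_idsn("drug(s) without targets passed to build_pharm_dsn: %s",
              paste(ids[n_targets == 0L], collapse = ","))
  seqs_per_drug <- lapply(profiles, function(p)
    vapply(p$targets, `[[`, character(1), "sequence"))
  uniq <- unique(unlist(seqs_per_drug))
  sim_u <- .norm_align_matrix(uniq, scoring)
  idx <- lapply(seqs_per_drug, match, uniq)
  n <- length(ids)
  m <- diag(1, n)
  agg <- if (aggregator == "max") max else mean
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- agg(sim_u[idx[[i]], idx[[j]], drop = FALSE])
  }
  similarity_network(m, ids = ids, source = "pharm", scale = "similarity",
                     meta = meta)
}

#' Split a cohort by target availability
#'
#' Fusion is defined only on drugs present in both views, so drugs with no
#' target sequences are retained in the chem-DSN but excluded from the
#' pharm-DSN and from fusion.
#'
#' @param profiles A `drug_cohort`.
#' @return List with `with_targets` and `without_targets` cohorts; the ids
#'   of excluded drugs are reported via `message()`.
#' @export
drugs_with_targets <- function(profiles) {
  has <- vapply(profiles, function(p) length(p$targets) > 0L, logical(1))
  if (any(!has))
    message(sprintf("excluding %d drug(s) without targets from pharm-DSN/fusion: %s",
                    sum(!has), paste(names(profiles)[!has], collapse = ",")))
  keep <- profiles[has]; drop <- profiles[!has]
  class(keep) <- class(drop) <- "drug_cohort"
  list(with_targets = keep, without_targets = drop)
}
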