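# Target-sequence similarity: pairwise protein alignment scores normalised
# by the geometric mean of the self-scores.

#' Alignment scoring parameters
#'
#' Affine-gap protein alignment scoring. A gap of length k costs
#' `|gap_open| + k * |gap_extend|` (the Biostrings convention). The
#' substitution matrix must be one shipped with Biostrings (e.g. BLOSUM62).
#'
#' @param substitution_matrix Matrix name, default `"BLOSUM62"`.
#' @param gap_open,gap_extend Strictly negative gap penalties (defaults -10
#'   and -0.5).
#' @param mode `"global"` (Needleman-Wunsch) or `"local"` (Smith-Waterman).
#' @return An `alignment_scoring` object.
#' @export
alignment_scoring <- function(substitution_matrix = "BLOSUM62",
                              gap_open = -10, gap_extend = -0.5,
                              mode = c("global", "local")) {
  mode <- match.arg(mode)
  if (gap_open >= 0 || gap_extend >= 0)
    stop_idsn("gap penalties must be strictly negative (got open=%g, extend=%g)",
              gap_open, gap_extend)
  mat <- .load_submat(substitution_matrix)
  if (max(abs(mat - t(mat))) > 0)
    stop_idsn("substitution matrix '%s' is not symmetric", substitution_matrix)
  obj <- list(substitution_matrix = substitution_matrix,
              gap_open = gap_open, gap_extend = gap_extend, mode = mode)
  class(obj) <- "alignment_scoring"
  obj
}

.load_submat <- function(name) {
  env <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = env)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || !exists(name, envir = env))
    stop_idsn("unknown substitution matrix '%s'", name)
  get(name, envir = env)
}

# Optimal pairwise alignment score under the scoring scheme.
.align_score <- function(a, b, scoring) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = .load_submat(scoring$substitution_matrix),
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend,
    type = scoring$mode, scoreOnly = TRUE)
}

# Vectorised: scores of many patterns against one subject.
.align_scores_vec <- function(patterns, subject, scoring) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(patterns), Biostrings::AAString(subject),
    substitutionMatrix = .load_submat(scoring$substitution_matrix),
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend,
    type = scoring$mode, scoreOnly = TRUE)
}

#' Normalised alignment similarity of two protein sequences
#'
#' `S(a,b) / sqrt(S(a,a) * S(b,b))` where S is the optimal alignment score
#' under `scoring` (self-scores use the same mode). Negative normalised
#' values are clamped to 0 so the result is a valid similarity for network
#' fusion; values are also capped at 1 (alignment scores are not an inner
#' product, so the raw ratio can marginally exceed 1 for near-duplicate
#' sequences).
#'
#' @param a,b Non-empty amino-acid sequences (20-letter alphabet plus X).
#' @param scoring An [alignment_scoring()].
#' @return Similarity in \[0, 1\].
#' @export
normalized_alignment_similarity <- function(a, b,
                                            scoring = alignment_scoring()) {
  .check_aa_sequence(a, "sequence a"); .check_aa_sequence(b, "sequence b")
  saa <- .align_score(a, a, scoring); sbb <- .align_score(b, b, scoring)
  if (saa <= 0 || sbb <= 0)
    stop_idsn("degenerate scoring: non-positive self-score (%g, %g)", saa, sbb)
  sab <- .align_score(a, b, scoring)
  min(1, max(0, sab / sqrt(saa * sbb)))
}

# All-pairs normalised similarity matrix over a set of sequences; one
# vectorised alignment call per subject keeps this O(n) calls.
.norm_align_matrix <- function(seqs, scoring) {
  n <- length(seqs)
  self <- vapply(seq_len(n), function(i) .align_score(seqs[[i]], seqs[[i]],
                                                      scoring), numeric(1))
  if (any(self <= 0))
    stop_idsn("degenerate scoring: non-positive self-score")
  m <- diag(1, n)
  if (n > 1) for (j in 2:n) {
    sc <- .align_scores_vec(unlist(seqs[1:(j - 1)]), seqs[[j]], scoring)
    vals <- pmin(1, pmax(0, sc / sqrt(self[1:(j - 1)] * self[j])))
    m[1:(j - 1), j] <- vals
    m[j, 1:(j - 1)] <- vals
  }
  m
}

#' Target-set similarity of two drugs
#'
#' Aggregates the normalised alignment similarities over all cross-pairs of
#' the two drugs' targets. `max` (default) calls two drugs similar when any
#' one target pair is highly similar; `mean` averages over all cross-pairs.
#'
#' @param A,B Drug profiles with at least one target each.
#' @param scoring An [alignment_scoring()].
#' @param aggregator `"max"` or `"mean"`.
#' @return Similarity in \[0, 1\].
#' @export
drug_pair_target_similarity <- function(A, B, scoring = alignment_scoring(),
                                        aggregator = c("max", "mean")) {
  aggregator <- match.arg(aggregator)
  if (length(A$targets) == 0L || length(B$targets) == 0L)
    stop_idsn("drug %s or %s has no targets",
              A$drug_id %||% "?", B$drug_id %||% "?")
  sims <- outer(seq_along(A$targets), seq_along(B$targets),
                Vectorize(function(i, j)
                  normalized_alignment_similarity(A$targets[[i]]$sequence,
                                                  B$targets[[j]]$sequence,
                                                  scoring)))
  if (aggregator == "max") max(sims) else mean(sims)
}
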