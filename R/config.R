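#' Pipeline configuration
#'
#' Bundles every tunable of the pipeline in one list so a single config
#' hash (recorded in every output header) identifies a run.
#'
#' @param L,r Fingerprint length and radius.
#' @param chem_metric `"cosine"` or `"tanimoto"`.
#' @param substitution_matrix,gap_open,gap_extend,align_mode Alignment
#'   scoring, see [alignment_scoring()].
#' @param aggregator Multi-target aggregation, `"max"` or `"mean"`.
#' @param fusion A [fusion_params()].
#' @param k Number of clusters.
#' @param seed Master random seed.
#' @param top_n Size of the top-pair list.
#' @param sim_threshold Candidate similarity cutoff in (0, 1).
#' @param n_perm Permutation count for the consistency test.
#' @return A `pipeline_config` list with a precomputed `hash` element.
#' @export
pipeline_config <- function(L = 2048L, r = 2L,
                            chem_metric = c("cosine", "tanimoto"),
                            substitution_matrix = "BLOSUM62",
                            gap_open = -10, gap_extend = -0.5,
                            align_mode = c("global", "local"),
                            aggregator = c("max", "mean"),
                            fusion = fusion_params(), k = 16L, seed = 1L,
                            top_n = 100L, sim_threshold = 0.7,
                            n_perm = 999L) {
  chem_metric <- match.arg(chem_metric)
  align_mode <- match.arg(align_mode)
  aggregator <- match.arg(aggregator)
  .assert_count(L, "L"); .assert_count(k, "k"); .assert_count(top_n, "top_n")
  .assert_count(n_perm, "n_perm")
  if (sim_threshold <= 0 || sim_threshold >= 1)
    stop_idsn("sim_threshold must be in (0,1)")
  cfg <- list(L = as.integer(L), r = as.integer(r),
              chem_metric = chem_metric,
              substitution_matrix = substitution_matrix,
              gap_open = gap_open, gap_extend = gap_extend,
              align_mode = align_mode, aggregator = aggregator,
              fusion = unclass(fusion), k = as.integer(k),
              seed = as.integer(seed), top_n = as.integer(top_n),
              sim_threshold = sim_threshold, n_perm = as.integer(n_perm))
  cfg$hash <- config_hash(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Scoring object from a pipeline config
#' @param cfg A [pipeline_config()].
#' @return An [alignment_scoring()].
#' @export
config_scoring <- function(cfg) {
  alignment_scoring(cfg$substitution_matrix, cfg$gap_open, cfg$gap_extend,
                    cfg$align_mode)
}
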