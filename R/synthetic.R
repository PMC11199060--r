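# Synthetic cohorts with planted cluster structure across both data views,
# so every pipeline stage is testable without any external database. A
# cohort is generated from per-cluster prototypes: a random fingerprint
# (Bernoulli bit density rho) and a random amino-acid sequence. Drugs
# perturb their cluster's prototypes -- independent bit flips at rate
# p_chem, independent residue substitutions at rate p_pharm -- and carry the
# cluster's pathway label, resampled uniformly over all labels with
# probability c (contamination). One master seed drives four named
# substreams (prototypes, chem noise, pharm noise, labels) so changing one
# rate does not shift the other components' draws.

#' Specification of a synthetic drug cohort
#'
#' Defaults loosely mirror a realistic anti-tumour screening cohort scale
#' (16 clusters of ~17 drugs, ~276 drugs); tests use a reduced 4 x 15
#' cohort for speed.
#'
#' @param n_clusters Number of planted clusters (>= 2).
#' @param drugs_per_cluster Scalar or length-`n_clusters` vector.
#' @param L Fingerprint length.
#' @param rho Prototype bit density in (0, 1).
#' @param p_chem Per-bit flip probability in \[0, 1).
#' @param target_length Prototype protein sequence length.
#' @param p_pharm Per-site substitution probability in \[0, 1).
#' @param c_contam Pathway label contamination rate in \[0, 1).
#' @param targets_per_drug Targets per drug (all derived from the cluster
#'   prototype).
#' @param seed Master seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_clusters = 16L, drugs_per_cluster = 17L,
                           L = 1024L, rho = 0.1, p_chem = 0.05,
                           target_length = 80L, p_pharm = 0.05,
                           c_contam = 0.1, targets_per_drug = 1L,
                           seed = 1L) {
  .assert_count(n_clusters, "n_clusters")
  if (n_clusters < 2L) stop_idsn("n_clusters must be >= 2")
  if (length(drugs_per_cluster) == 1L)
    drugs_per_cluster <- rep(drugs_per_cluster, n_clusters)
  if (length(drugs_per_cluster) != n_clusters)
    stop_idsn("drugs_per_cluster must be scalar or length n_clusters")
  for (x in drugs_per_cluster) .assert_count(x, "drugs_per_cluster")
  .assert_count(L, "L"); .assert_count(target_length, "target_length")
  .assert_count(targets_per_drug, "targets_per_drug")
  for (r in c(p_chem = p_chem, p_pharm = p_pharm, c_contam = c_contam))
    if (r < 0 || r >= 1) stop_idsn("rates must lie in [0,1)")
  if (rho <= 0 || rho >= 1) stop_idsn("rho must lie in (0,1)")
  obj <- list(n_clusters = as.integer(n_clusters),
              drugs_per_cluster = as.integer(drugs_per_cluster),
              L = as.integer(L), rho = rho, p_chem = p_chem,
              target_length = as.integer(target_length), p_pharm = p_pharm,
              c_contam = c_contam,
              targets_per_drug = as.integer(targets_per_drug),
              seed = as.integer(seed))
  class(obj) <- "synthetic_spec"
  obj
}

# 20 standard amino acids (utils.R loads after this file, so spelled out)
AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V")

.mutate_seq <- function(chars, p) {
  hit <- stats::runif(length(chars)) < p
  if (any(hit))
    chars[hit] <- vapply(chars[hit], function(a)
      sample(setdiff(AA20, a), 1L), character(1))
  chars
}

#' Generate a synthetic drug cohort with ground truth
#'
#' @param spec A [synthetic_spec()].
#' @param shared_chem_prototype,shared_pharm_prototype Optional integer
#'   vectors of cluster indices forced to share one prototype in the given
#'   view (used by [planted_two_view_benchmark()] to make a view blind to a
#'   cluster pair).
#' @return List with `profiles` (a fingerprinted `drug_cohort` whose
#'   `structure` fields are fingerprint bitstrings) and `truth` (list:
#'   `clusters` named integer vector drug -> true cluster 1..n_clusters,
#'   `cluster_pathways` named character vector cluster -> pathway label).
#' @export
generate_cohort <- function(spec, shared_chem_prototype = integer(0),
                            shared_pharm_prototype = integer(0)) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  K <- spec$n_clusters
  n <- sum(spec$drugs_per_cluster)
  cluster_of <- rep(seq_len(K), spec$drugs_per_cluster)
  ids <- sprintf("d%03d", seq_len(n))
  labels_all <- sprintf("PW%02d", seq_len(K))

  # substream 1: prototypes
  set.seed(.substream_seed(spec$seed, 1L))
  proto_fp <- lapply(seq_len(K), function(k) {
    repeat {
      b <- as.integer(stats::runif(spec$L) < spec$rho)
      if (sum(b) > 0) return(b)
    }
  })
  proto_seq <- lapply(seq_len(K), function(k)
    sample(AA20, spec$target_length, replace = TRUE))
  for (k in shared_chem_prototype[-1]) proto_fp[[k]] <-
    proto_fp[[shared_chem_prototype[[1]]]]
  for (k in shared_pharm_prototype[-1]) proto_seq[[k]] <-
    proto_seq[[shared_pharm_prototype[[1]]]]

  # substream 2: chem noise
  set.seed(.substream_seed(spec$seed, 2L))
  fps <- lapply(seq_len(n), function(i) {
    b <- proto_fp[[cluster_of[i]]]
    flip <- stats::runif(spec$L) < spec$p_chem
    b2 <- ifelse(flip, 1L - b, b)
    if (sum(b2) == 0L) b2[sample.int(spec$L, 1L)] <- 1L
    as.integer(b2)
  })

  # substream 3: pharm noise
  set.seed(.substream_seed(spec$seed, 3L))
  targets <- lapply(seq_len(n), function(i) {
    lapply(seq_len(spec$targets_per_drug), function(t)
      list(target_id = sprintf("%s_t%d", ids[i], t),
           sequence = paste(.mutate_seq(proto_seq[[cluster_of[i]]],
                                        spec$p_pharm), collapse = "")))
  })

  # substream 4: label contamination
  set.seed(.substream_seed(spec$seed, 4L))
  pathway <- labels_all[cluster_of]
  contam <- stats::runif(n) < spec$c_contam
  pathway[contam] <- sample(labels_all, sum(contam), replace = TRUE)

  profiles <- lapply(seq_len(n), function(i) {
    fp <- list(bits = fps[[i]], L = spec$L, r = 0L)
    class(fp) <- "fingerprint"
    list(drug_id = ids[i], structure = paste(fps[[i]], collapse = ""),
         fingerprint = fp, targets = targets[[i]], pathway = pathway[i],
         extra_annotations = list())
  })
  names(profiles) <- ids
  class(profiles) <- "drug_cohort"
  truth <- list(clusters = stats::setNames(cluster_of, ids),
                cluster_pathways = stats::setNames(labels_all, seq_len(K)))
  list(profiles = profiles, truth = truth)
}

#' Two-view planted benchmark for the fusion-benefit experiment
#'
#' Builds chem- and pharm-DSNs from one synthetic cohort and degrades the
#' selected view(s). `"chem"`/`"pharm"`: the named view is rebuilt with
#' near-random noise (flip rate 0.5 / substitution rate 0.9), destroying
#' its cluster signal. `"both-complementary"` (requires 4 clusters): the
#' chem view is built blind to the (1,2) cluster pair (clusters 1 and 2
#' share one fingerprint prototype) and the pharm view blind to (3,4), so
#' each single view can recover only 3 of the 4 clusters and fusion is
#' strictly informative.
#'
#' @param spec A [synthetic_spec()].
#' @param degrade `"chem"`, `"pharm"`, `"both-complementary"`, or `"none"`.
#' @param scoring Alignment scoring for the pharm view. The default is
#'   *local* alignment: under global alignment, unrelated random protein
#'   prototypes score non-positively, the normalised similarity clamps to
#'   exactly 0, and the pharm view becomes a disconnected graph whose
#'   spectral clustering is undefined. Local alignment keeps a weak
#'   positive background similarity between families, as residual homology
#'   does in real target sets, so each single view is clusterable on its
#'   own.
#' @return List with `chem`, `pharm` ([similarity_network()]s), `truth`,
#'   and `profiles`.
#' @export
planted_two_view_benchmark <- function(spec,
                                       degrade = c("both-complementary",
                                                   "chem", "pharm", "none"),
                                       scoring = alignment_scoring(mode = "local")) {
  degrade <- match.arg(degrade)
  shared_c <- integer(0); shared_p <- integer(0)
  if (degrade == "both-complementary") {
    if (spec$n_clusters != 4L)
      stop_idsn("both-complementary degradation requires exactly 4 clusters")
    shared_c <- c(1L, 2L); shared_p <- c(3L, 4L)
  } else if (degrade == "chem") {
    spec$p_chem <- 0.5
  } else if (degrade == "pharm") {
    spec$p_pharm <- 0.9
  }
  cohort <- generate_cohort(spec, shared_chem_prototype = shared_c,
                            shared_pharm_prototype = shared_p)
  chem <- build_chem_dsn(cohort$profiles, metric = "cosine",
                         meta = list(seed = spec$seed))
  pharm <- build_pharm_dsn(cohort$profiles, scoring = scoring,
                           aggregator = "max",
                           meta = list(seed = spec$seed))
  list(chem = chem, pharm = pharm, truth = cohort$truth,
       profiles = cohort$profiles)
}

#' Write a synthetic cohort in the exact formats the readers consume
#'
#' Emits `drugs.csv` (drug_id, structure bitstring, pathway),
#' `targets.fasta` (headers `drug_id|target_id`), `pathway.csv` (drug_id,
#' pathway) and `truth.csv` (drug_id, cluster) into `out_dir`.
#'
#' @param profiles,truth Output of [generate_cohort()].
#' @param out_dir Output directory; must be empty or absent unless
#'   `force = TRUE`.
#' @param force Overwrite a non-empty directory.
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(profiles, truth, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0L && !force)
    stop_idsn("output directory %s is not empty (use force = TRUE)", out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ids <- names(profiles)
  pw <- vapply(profiles, function(p) p$pathway %||% NA_character_,
               character(1))
  drugs <- data.frame(drug_id = ids,
                      structure = vapply(profiles, `[[`, character(1),
                                         "structure"),
                      pathway = ifelse(is.na(pw), "", pw))
  utils::write.csv(drugs, file.path(out_dir, "drugs.csv"),
                   row.names = FALSE, quote = FALSE)
  con <- file(file.path(out_dir, "targets.fasta"), "wt")
  for (p in profiles) for (t in p$targets) {
    writeLines(sprintf(">%s|%s", p$drug_id, t$target_id), con)
    writeLines(t$sequence, con)
  }
  close(con)
  utils::write.csv(data.frame(drug_id = ids, pathway = pw),
                   file.path(out_dir, "pathway.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(data.frame(drug_id = ids,
                              cluster = unname(truth$clusters[ids])),
                   file.path(out_dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(out_dir)
}
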