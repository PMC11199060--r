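Package: idsn
Title: Multiscale Drug Similarity Network Fusion for Drug Repositioning
Version: 0.1.0
Authors@R:
    person("iDSN", "Developers", email = "idsn@example.org", role = c("aut", "cre"))
Description: Builds single-property drug similarity networks (DSNs) from
    chemical structure fingerprints and drug target protein sequences, fuses
    them into an integrated DSN (iDSN) with similarity network fusion
    (nonlinear cross-diffusion), clusters the fused network by spectral
    clustering, evaluates partitions with internal and external validity
    indices (adjusted Rand index, normalised mutual information, silhouette,
    Davies-Bouldin, Calinski-Harabasz), attributes fused edges to their
    source data type, and derives drug repositioning candidates from the
    pathway (in)consistency of highly similar drug pairs, including a
    permutation significance test and hypergeometric gene-set enrichment.
    Ships a synthetic cohort generator with planted cluster structure so the
    full pipeline is testable without any external database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
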