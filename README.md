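# idsn — multiscale drug similarity network fusion for drug repositioning

`idsn` is an R package for scientists who want to integrate heterogeneous
drug attribute data — chemical structure and target protein sequence — into
a single drug similarity network and mine it for repositioning leads. No
single data view tells the whole story: two drugs can share a scaffold but
hit unrelated targets, or hit the same kinase from unrelated chemotypes.
The package builds one drug similarity network (DSN) per view, fuses them
nonlinearly, and asks where high similarity and pathway annotation
*disagree* — those pairs are the repositioning candidates.

## The method

1. **chem-DSN.** Each drug's structure (SMILES or precomputed fingerprint
   bitstring) is vectorised into a hashed circular-substructure binary
   fingerprint (radius 2, length 2048 by default) and compared by the
   vector-space cosine `s(u,v) = u·v / (‖u‖‖v‖)` (Tanimoto
   `|u∧v|/|u∨v|` optional).
2. **pharm-DSN.** Drug pairs are compared through their target proteins:
   the optimal pairwise alignment score (BLOSUM62, affine gaps −10/−0.5)
   normalised by the geometric mean of self-scores,
   `s(a,b) = S(a,b)/√(S(a,a)·S(b,b))`, aggregated over target cross-pairs
   (max by default).
3. **Fusion (SNF).** The two DSNs are fused by similarity network fusion:
   per-view scaled-exponential affinity kernels
   `W_ij = exp(−d_ij²/(μ·ε_ij))` with a KNN-adaptive bandwidth, a
   row-stochastic full kernel `P` and a sparse K-nearest-neighbour kernel
   `S`, then `T` rounds of cross-diffusion
   `P⁽ᵛ⁾ ← S⁽ᵛ⁾ · mean(P⁽ᵘ⁾, u≠v) · S⁽ᵛ⁾ᵀ`. The average of the converged
   views is the integrated DSN (iDSN).
4. **Clustering and validation.** Spectral clustering on the symmetric
   normalised Laplacian (k-means++ on the row-normalised eigenvector
   embedding), eigengap diagnostics for k, and validity indices: adjusted
   Rand index and normalised mutual information against external
   annotations; silhouette, Davies–Bouldin and Calinski–Harabasz
   internally.
5. **Repositioning analyses.** Per-cluster attribution of fused edges to
   chemical structure / drug targets / fusion value (rank-based);
   pathway-consistency of the top similar pairs with a per-cluster
   label-permutation significance test; candidate pairs = inconsistent
   pairs above a similarity threshold (default 0.7); hypergeometric
   enrichment of cluster target sets against user-supplied GMT
   collections with Benjamini–Hochberg adjustment.

A synthetic cohort generator (`generate_cohort()`,
`planted_two_view_benchmark()`) plants cluster structure in both views —
correlated fingerprints, mutated target sequences, contaminated pathway
labels — so the whole pipeline is testable offline.

## Worked example

```r
library(idsn)

spec   <- synthetic_spec(n_clusters = 4, drugs_per_cluster = 15,
                         c_contam = 0.2, seed = 42)
cohort <- generate_cohort(spec)
chem   <- build_chem_dsn(cohort$profiles)
pharm  <- build_pharm_dsn(cohort$profiles,
                          scoring = alignment_scoring(mode = "local"))
fused  <- snf(list(chem, pharm), fusion_params(K = 20, mu = 0.5, T = 20))
fused
#> <similarity_network> source=fused scale=similarity n=60 drugs
#>   off-diagonal: min=0.026 mean=0.2772 max=1

res <- spectral_cluster(fused, k = 4, seed = 42)
adjusted_rand_index(res$labels, cohort$truth$clusters)
#> [1] 1
eigengap_candidates(fused, kmax = 8)[1, ]
#>   k       gap
#> 3 4 0.7203031
```

The fused network recovers the four planted clusters perfectly (ARI = 1)
and the eigengap ranks k = 4 first with a dominant gap. Downstream:

```r
top   <- top_similar_pairs(fused, 100)
annot <- annotation_table("pathway",
                          vapply(cohort$profiles, `[[`, character(1), "pathway"))
pathway_consistency(top, annot)$fraction
#> [1] 0.78
head(repositioning_candidates(fused, annot, sim_threshold = 0.7), 3)
#>   drug_i drug_j similarity pathway_i pathway_j
#> 1   d033   d042  1.0000000      PW01      PW03
#> 2   d033   d045  0.9999328      PW01      PW03
#> 3   d033   d034  0.9988724      PW01      PW03
```

78% of the top-100 pairs have consistent pathway labels — close to the
(1−c)² + resampling-correction expectation of 0.73 under the 20% label
contamination this cohort was generated with. The inconsistent
high-similarity pairs (here drugs whose labels were contaminated away from
their cluster's pathway) are exactly what the candidate list surfaces: each
row suggests the partner's pathway as the drug's potential pathway.

```r
att <- edge_source_attribution(fused, chem, pharm, res$labels)
round(cluster_contribution_report(att, res$labels)$global, 2)
#> chemical_structure       drug_targets       fusion_value
#>              44.52              44.52              10.95
```

On this balanced synthetic cohort both views contribute equally; on real
cohorts the report quantifies which data type drives each cluster.

## Command line

Every stage is also a subcommand of the installed `exec/idsn` script
(`simulate`, `build-chem`, `build-pharm`, `fuse`, `cluster`, `evaluate`,
`contribute`, `pairs`, `candidates`, `enrich`), reading and writing
plain-text TSV/CSV/FASTA/GMT with metadata headers (seed, config hash), so
reruns with the same seed are byte-identical:

```sh
idsn simulate --clusters 4 --per-cluster 15 --seed 7 --out fixtures/
idsn build-chem  --drugs fixtures/drugs.csv --seed 7 --out chem.tsv
idsn build-pharm --drugs fixtures/drugs.csv --fasta fixtures/targets.fasta --seed 7 --out pharm.tsv
idsn fuse --k 20 --mu 0.5 --iterations 20 --seed 7 --out idsn.tsv chem.tsv pharm.tsv
idsn cluster --k 4 --seed 7 --out labels.tsv idsn.tsv
idsn pairs --net idsn.tsv --top 100 --annot fixtures/pathway.csv --seed 7 --out pairs.tsv
```

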