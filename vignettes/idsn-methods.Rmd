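---
title: "idsn: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{idsn: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idsn)
```

# The problem

Drug repositioning asks whether an approved or investigational compound can
act through a pathway other than its annotated one. Any single drug
similarity measure is partial: structural fingerprints capture chemotype
but not mechanism; target-sequence similarity captures mechanism but is
blind to scaffold. `idsn` integrates the two into one network and treats
*disagreement* between high network similarity and pathway annotation as
the repositioning signal.

# Models and assumptions

## Chemical view

Structures are vectorised as hashed circular substructures (ECFP-style):
every atom-centred neighbourhood of radius $0..r$ is canonically hashed
into a length-$L$ bit vector. Defaults $r = 2$, $L = 2048$ are the field
standard. The SMILES reader is topological only — no valence or
implicit-hydrogen model, no canonical aromaticity perception — which is
sufficient for a deterministic vector-space representation but is *not* a
chemistry engine; cohorts with precomputed fingerprint bitstrings bypass
it entirely. The default similarity is the cosine
$s(u,v) = u \cdot v / (\lVert u\rVert \lVert v\rVert)$ (the literal
vector-space-model similarity); Tanimoto is config-selectable. For binary
vectors, cosine $\ge$ Tanimoto entrywise, so the choice shifts the scale
but rarely the ranking.

## Pharmacological view

Target sequences are compared by optimal pairwise alignment (Biostrings;
BLOSUM62, affine gaps: a gap of length $k$ costs $10 + 0.5k$), normalised
by the geometric mean of self-scores:
$s(a,b) = S(a,b)/\sqrt{S(a,a)\,S(b,b)}$, clamped to $[0,1]$. The lower
clamp (negative scores $\to 0$) is required because the fusion step needs
non-negative similarities; the upper clamp guards the rare case where the
ratio marginally exceeds 1 (alignment scores are not an inner product, so
Cauchy–Schwarz does not apply). Multi-target drugs are aggregated over
target cross-pairs with `max` by default: sharing *one* highly similar
target is taken as pharmacological similarity; `mean` is offered for
sensitivity analysis. An important, deliberate interpretation: pairwise
global alignment stands in for "multiple sequence alignment" because an
MSA does not directly yield a pairwise similarity in $[0,1]$.

Global alignment of *unrelated* sequences normally scores non-positively,
so between-family pharm similarities clamp to exactly 0. That is faithful,
but it can leave the pharm-DSN disconnected, and spectral clustering of a
disconnected graph is deliberately a hard error (the component structure,
not the eigensolver, should decide k). Where a single view must be
clustered on its own — notably the synthetic two-view benchmark — local
alignment is used instead: it keeps a weak positive background similarity
between families, much as residual homology does among real kinase
targets.

## Fusion

The two DSNs are fused by similarity network fusion (nonlinear
cross-diffusion). Per view: distances $d_{ij} = \sqrt{2(1 - s_{ij})}$ (the
chordal distance between unit vectors with cosine $s$), affinities
$W_{ij} = \exp(-d_{ij}^2 / (\mu\,\varepsilon_{ij}))$ with the KNN-adaptive
bandwidth $\varepsilon_{ij} = (\bar d_i + \bar d_j + d_{ij})/3 +
\varepsilon_{\mathrm{reg}}$, a full kernel $P_{ij} = W_{ij} / (2\sum_{k\ne
i} W_{ik})$, $P_{ii} = 1/2$, and a sparse local kernel supported on the
$K$ nearest neighbours. Then $T$ rounds of
$P^{(v)} \leftarrow S^{(v)} \overline{P^{(u \ne v)}} S^{(v)\top}$ with
re-normalisation. These formulas follow the canonical SNF construction
that the method invokes; they are re-derived and tested here (kernel
formulas against direct hand evaluation, the update against its
contract properties), not wrapped from an external implementation.

Defaults $K = 20$ (capped at $n-1$), $\mu = 0.5$, $T = 20$,
$\varepsilon_{\mathrm{reg}} = 10^{-8}$: the standard SNF settings, all
config-exposed, since no values are fixed by the source method.
Post-processing: the view-averaged matrix is symmetrised, off-diagonal
entries rescaled by their maximum, diagonal set to 1 — a documented
convention so downstream consumers always see a similarity in $[0,1]$.
Ties at the $K$-th neighbour are broken by id order for cross-platform
determinism.

## Clustering and metrics

Spectral clustering uses the symmetric normalised Laplacian
$L = I - D^{-1/2} W D^{-1/2}$, the row-normalised first-$k$ eigenvector
embedding, and k-means with k-means++ seeding, 10 restarts, and a fixed
seed. Determinism is engineered in three places: eigenvector signs are
fixed (largest-magnitude entry positive), k-means restarts share one
seeded RNG stream, and output labels are renumbered by descending cluster
size. $k$ defaults to 16, mirroring the cohort scale the method was
designed around; the eigengap ranking (`eigengap_candidates()`) is
guidance only, because a fixed k was part of the original design.

External validity uses ARI (pair-counting, chance-corrected) and NMI
(geometric-mean normalisation by default; arithmetic offered — the choice
is not fixed by the source method). Internal validity: silhouette on
$1 - s$ distances directly; Davies–Bouldin and Calinski–Harabasz on the
spectral embedding coordinates, because both need centroids in a vector
space and no embedding choice is prescribed — this is a documented
interpretation.

## Edge attribution

After fusion, the chem, pharm and fused matrices live on different scales,
so raw-value comparison of an edge across networks is meaningless. Each
network's off-diagonal entries are therefore rank-transformed to $[0,1]$
and a within-cluster edge is attributed to the view with the larger rank;
if the fused rank beats both views by more than `margin` (default 0.05),
the edge is a *fusion value* edge — strong only because the views
reinforced each other. Exact chem/pharm rank ties also go to fusion value.
The attribution rule is an interpretation (the original rule is not
printed); the margin is config-exposed.

## Consistency statistics and candidates

The top-$n$ pair list is ranked by fused similarity with lexicographic tie
breaks. Pathway consistency is the fraction of annotated pairs with
identical labels. Per-cluster significance uses a seeded label-permutation
test — assumption-free and matching the "significance difference" framing
— with the add-one estimator $p = (1 + \#\{\text{null} \ge
\text{obs}\})/(1 + n_{\mathrm{perm}})$, bounded below by
$1/(n_{\mathrm{perm}}+1)$ and slightly conservative under ties.
Repositioning candidates are annotated pairs with fused similarity
*strictly* greater than the threshold (default 0.7) and differing labels;
the partner's label is reported as the drug's potential pathway.

Enrichment is a plain upper-tail hypergeometric test (including the
observed overlap, so zero overlap gives $p = 1$) of cluster target sets
against user-supplied GMT collections, BH-adjusted across all rows. There
is no live GO/KEGG retrieval and no DAG-aware propagation, by design:
reproducibility without network access.

# The synthetic world

`generate_cohort()` plants $K$ clusters: per cluster a prototype
fingerprint (independent Bernoulli bits, density $\rho = 0.1$) and a
prototype protein sequence (uniform over the 20 amino acids). Each drug
flips prototype bits independently at rate $p_{\mathrm{chem}}$, mutates
each prototype residue at rate $p_{\mathrm{pharm}}$ (uniform over the 19
alternatives), and carries its cluster's pathway label, resampled
uniformly over all labels with probability $c$. One master seed drives
four named substreams (prototypes, chem noise, pharm noise, labels) so
changing one rate leaves the other components' draws untouched.

Default scale loosely mirrors a realistic anti-tumour screening cohort
(16 clusters × 17 drugs ≈ 272 drugs); tests run 4 × 15 = 60 for speed.
Default noise ($p_{\mathrm{chem}} = p_{\mathrm{pharm}} = 0.05$, $c = 0.1$,
one target per drug, prototype length 80) gives strong but not degenerate
structure: within-cluster fingerprint cosine clearly above between-cluster,
alignment similarity within families near 1.

What the generator does *not* emulate: valence-aware chemistry (bit flips
are not chemical edits), real protein families (mutations are uniform, not
BLOSUM-weighted), correlated annotation errors, and heavy-tailed cluster
sizes. A green test therefore establishes algorithmic correctness and the
fusion benefit *on planted structure*, not performance on any real cohort.

The two-view benchmark (`planted_two_view_benchmark()`) implements
complementary degradation by prototype sharing: clusters 1 and 2 share the
chem prototype, clusters 3 and 4 the pharm prototype, so each view is
exactly blind to one cluster pair, each single view tops out around ARI
$\approx 0.66$ with $k = 4$, and only the fusion can recover all four
clusters. This is parameter-free and makes the fusion benefit a structural
fact of the world rather than a noise-level tuning.

# Numerical choices and degenerate inputs

* Symmetry is enforced at construction (`(M + M^\top)/2` after a
  $10^{-10}$ asymmetry check); file round-trips are exact to $10^{-12}$
  with deterministic `%.15g` formatting, so identical seeds give
  byte-identical outputs.
* Isolated nodes (zero off-diagonal affinity) are a hard error naming the
  drug, as is a disconnected graph at embedding time (component sizes
  reported).
* $k = n$ clustering bypasses k-means (every drug its own cluster);
  silhouette of singleton clusters contributes 0; Davies–Bouldin treats
  coincident centroids with zero spread as ratio 0 (duplicated points)
  and otherwise as Inf.
* Duplicate points in SNF are handled by
  $\varepsilon_{\mathrm{reg}} = 10^{-8}$ in the kernel bandwidth.
* Drugs without targets are kept in the chem-DSN but excluded (with an
  explicit report) from the pharm-DSN and fusion: fusion is defined only
  on drugs present in both views.

# Known limitations

* The SMILES reader covers the organic subset, brackets, branches and
  ring closures; exotic SMILES (reaction, polymer, isotope-sensitive
  cases) are out of scope, and hashed-fingerprint bits are not aligned
  with any published ECFP implementation (deterministic within this
  package only).
* Alignment cost is quadratic in cohort size; sequences are deduplicated
  before alignment, but cohorts beyond a few thousand drugs need a
  batched backend.
* The permutation p-value is conservative under heavy ties (few pairs per
  cluster); a binomial approximation is not provided.
* Fusion is limited to the two-view case plus equal view weighting;
  heterogeneous multi-omics weighting is out of scope.
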