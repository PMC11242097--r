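---
title: "Methods: from staged expression profiles to drug-combination predictions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from staged expression profiles to drug-combination predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mclnet)
```

`mclnet` implements a modular analysis for staged lymphoid malignancies —
mantle cell lymphoma being the motivating disease, with its progression
from in situ through classical and intermediate to aggressive stages. The
pipeline takes log2-scale expression matrices with stage labels and ends
with predicted drug combinations. This vignette explains each model, the
tunable parameters and why their defaults are what they are, what the
synthetic generators do and do not emulate, and the numerical conventions.

## Preprocessing and sample diagnostics

Microarray compendia mix platforms and batches, and stage labels assigned
by morphology can be wrong. Three tools address this:

* `quantile_normalize()` maps every sample onto the across-sample mean of
  order statistics. Ties receive the mean of their tied reference values,
  which makes the operation idempotent.
* `batch_center()` shifts each batch's per-gene mean to the gene's grand
  mean. This is deliberately the simplest additive correction: platform-
  trained batch models do not transfer across studies, so the package
  corrects only additive offsets and accepts an externally corrected
  matrix through `expression_dataset()` for anything richer.
* `svm_regroup()` retrains linear support-vector machines on bootstrap
  resamples (stratified by group, with replacement) of the non-held-out
  groups, using the `k_top = 500` most variable training genes, and
  predicts each held-out sample. A sample is reassigned to its majority
  label when the frequency reaches `threshold = 0.75`, otherwise excluded
  from downstream contrasts. The kernel (linear), cost (package default)
  and bootstrap count (100) are conventions, not fitted quantities; the
  0.75 threshold mirrors requiring a three-of-four majority.

Sample structure is visualized through `mds_distances()` — the
root-mean-square of the `k_top` largest absolute log2 differences per
sample pair, a "leading fold change" metric that emphasizes the genes
actually separating two samples — followed by `classical_mds()`
(double-centered Gram eigendecomposition; negative-eigenvalue dimensions
are dropped with a warning because such distances are non-Euclidean).

## Moderated differential expression

Stage contrasts here are all two-group comparisons with few samples per
group, where per-gene variance estimates are unstable. `moderated_t_test()`
shrinks the pooled two-group variance $s_g^2$ (on $d_g = n_1+n_2-2$ df)
toward a scaled-F prior. The hyperparameters are estimated by
moment-matching $\log s_g^2$: the excess of $\mathrm{var}(\log s_g^2)$
over $\psi'(d_g/2)$ determines $d_0$ through the inverse trigamma, and
the mean equation gives $s_0^2$. Then

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\qquad
\tilde t_g = \frac{\mathrm{logFC}_g}{\tilde s_g\sqrt{1/n_1+1/n_2}}$$

on $d_0 + d_g$ df. Zero-variance genes remain testable because the prior
keeps $\tilde s_g^2$ positive; a dataset where *every* gene has zero
variance leaves the hyperparameters undefined and errors. The default
significance rule is adjusted p < 0.05 (Benjamini–Hochberg); a raw-p rule
is available via `top_degs(use_adjusted = FALSE)` because both conventions
circulate for this kind of analysis. Ties in raw p are broken by |logFC|
descending, then gene id, so disease modules are reproducible.
`top_degs()` returns *all* passing genes when fewer than `n` pass — an
early-stage contrast with 27 significant genes yields a 27-gene module
even at `n = 100`.

## Mutual-information co-expression networks

Correlation misses non-linear co-regulation, so condition-specific
networks are built from Kraskov k-nearest-neighbour mutual information
(`knn_mutual_information()`, algorithm 1, max-norm neighbourhoods):

$$\hat I = \psi(k) + \psi(N) - \big\langle \psi(n_x+1)+\psi(n_y+1)\big\rangle$$

with `k_nn = 3`, the customary default balancing bias and variance at the
sample sizes of microarray groups. The estimator is undefined under heavy
ties, so tied vectors receive deterministic sub-noise jitter (uniform on
$(0, 10^{-10})$, seeded from the gene index inside `mi_matrix()`), which
preserves determinism and exact symmetry. Estimates are used raw — no
Fisher-z normalization — and negative null-range estimates are clamped to
0 in the matrix.

`mrnetb()` turns the MI matrix into an inferred network. For each target
$Y$ it seeks the predictor subset maximizing

$$J(S) = \sum_{X_i \in S} I(X_i;Y) - \frac{1}{|S|}\sum_{X_i < X_j \in S} I(X_i;X_j).$$

The search is backward elimination followed by sequential replacement.
Two numerical choices matter. First, the elimination phase walks the full
greedy removal path and keeps the best subset seen, rather than stopping
at the first non-improving removal: the objective can plateau at the full
predictor set (no single removal improves although removing two does),
and early stopping strands the search there. Second, the replacement
phase applies the best of the single-variable moves — swap one in for one
out, drop one, add one — until none improves $J$. On random 6-gene
problems this search attains the exhaustive-subset optimum in more than
99.9% of instances, which the test suite verifies directly against
enumeration. Each selected predictor scores its relevance minus its mean
redundancy to the rest of the final subset; the undirected weight is the
larger directional score, clamped at zero, so weights never exceed the
underlying MI.

`hard_threshold(q = 0.95)` binarizes the weighted network at the `q`-th
quantile of the strictly positive weights. Published analyses of this
kind used per-network quantiles between 0.93 and 0.98 without a stated
selection rule, so `q` is per-network configuration with 0.95 as the
midpoint default; `q = 0` keeps every positive edge. Genes unconnected in
*both* of a pair of networks carry no alignment information and are
removed by `prune_isolated()` — a gene connected in either network is
kept in both.

## Cross-network module alignment

To find co-expression modules shared or rewired between two conditions,
`build_joint_graph()` duplicates every gene — one copy per network — and
couples the copies with weight $\beta$, giving the block matrix
$[[A_A, \beta I], [\beta I, A_B]]$. Spectral clustering of the symmetric
normalized Laplacian $L = I - D^{-1/2} W D^{-1/2}$ (Ng–Jordan–Weiss:
row-normalized embedding, seeded k-means with 10 restarts) then groups
gene copies jointly across networks; a cluster's two per-network member
sets need not coincide, and the module is their union.

The cluster count comes from the eigengap
(`select_k_eigengap`, default range 2–30): $k$ maximizes
$\lambda_{k+1}-\lambda_k$ among the smallest Laplacian eigenvalues, ties
to the smaller $k$.

**Choosing $\beta$.** The default is 1.0, but $\beta$ must be read
relative to within-network degree: after degree normalization a coupling
of 1 against a within-module degree of ~17 contributes little, the two
copies of a module separate in the embedding, and the eigengap reports
twice the module count. Coupling on the order of the within-module degree
(e.g. $\beta = 5$ for the planted-partition experiments in the tests,
where blocks of 30 genes connect with probability 0.6) makes each gene's
copies cohere and the eigengap recovers the planted model order. This
mirrors the per-comparison calibration such alignments need in practice;
$\beta$ and `q` are therefore first-class configuration.

`filter_modules()` applies the size bounds 8–800 on the gene union, drops
connected components below `small_component_cutoff = 3` nodes inside the
union-induced subgraph (edges present in either network), and requires
members from both networks. `coexpression_fold_change()` annotates each
surviving edge with $\log_2((MI_B+\varepsilon)/(MI_A+\varepsilon))$,
$\varepsilon = 10^{-6}$ (well below real MI values, large enough to keep
zero-MI edges finite); negative values mean loss of co-expression from
condition A to B. Only pairwise alignment is implemented.

## Enrichment

`ora()` is a generic over-representation test: upper-tail hypergeometric
p-value for the overlap k between a query and each gene set within a
universe (default: all genes on the matrix, the standard ORA background),
fold enrichment $FE = (k/n)/(K/N)$, BH adjustment across tested sets.
`pathway_graph()` joins significant sets sharing overlapping query genes
(edge weight = shared-gene count) — early-stage contrasts typically give
small graphs threaded through one hub gene, the pattern this view is
designed to expose. Active-subnetwork search and identifier mapping, as
provided by dedicated enrichment tools, are intentionally out of scope;
`fe_matrix()` exports the FE-by-contrast matrix those tools' heatmaps are
built from.

## Drug repurposing

`propose_drugs()` intersects a drug catalog's "target"-category
interactions of approved drugs with a contrast's top DEGs and applies the
direction rule (`action_compatible()`): enhancing actions (activator,
agonist, partial agonist, plus the configurable extensions stimulator,
inducer, potentiator) are excluded for up-regulated genes; suppressing
actions (inhibitor, antagonist, plus blocker, suppressor, negative
allosteric modulator, antisense) for down-regulated genes; unspecified
actions are kept, because an untyped target interaction is not evidence
of the wrong direction. A pair with several actions is excluded when
*any* action is incompatible (the strict reading; `mode = "all"` relaxes
it). Indication tags are pass-through metadata, never computed.

## Drug-combination screening

`screen_combinations()` implements network-proximity screening on the
interactome's largest connected component (nodes outside it are dropped
with logged counts — shortest-path distances are undefined across
components). Drugs need at least two mapped targets. Two measures drive
the classification:

* **Separation** $s_{AB} = \langle d_{AB}\rangle - (\langle d_{AA}\rangle +
  \langle d_{BB}\rangle)/2$, closest-distance averages over both target
  sets; internal distance of a singleton set is 0. Negative separation
  means topologically overlapping target neighbourhoods.
* **Proximity z-score** of a drug's targets T to the disease module D:
  observed $d(T,D) = \frac{1}{|T|}\sum_t \min_g d(t,g)$ against a null
  that redraws both sets with matched sizes and degree profiles
  (`n_perm = 1000` default). Degree matching uses $\log_2$-width degree
  bins merged upward until each holds ≥ 25 nodes, sampling without
  replacement — hubs are compared with hubs, not with leaves. A constant
  null (possible on tiny fixtures) yields ±Inf/0 with a degenerate flag.
  The asymmetric closest measure is the screening convention; the
  symmetric variant is one flag away in `separation()` users can apply.

`classify_principle()` maps the signs $(s_{AB}, z_A, z_B)$ onto six
exposure principles. Boundaries: $z = 0$ counts as *not* overlapping the
disease module and $s = 0$ as separated, so "complementary exposure" —
the configuration predictive of effective combinations — requires strict
disease overlap of both drugs ($z_A < 0$, $z_B < 0$) with non-overlapping
targets ($s_{AB} \ge 0$). Effective pairs feed a target–target network
(all cross-drug pairs of distinct genes) naming the gene pairs to hit
simultaneously, and a dual matrix (separations below the diagonal,
principles above) for heatmap-style summaries.

The disease module defaults to the top 100 DEGs of a contrast; reported
analyses of this design used both 100 and 200, so the size is a
parameter (`top_n`).

## Synthetic data: what it does and does not show

`simulate_expression()` builds values as baseline + DE shift +
latent-factor module signal + batch offset + Gaussian noise on the log2
scale. Co-expression modules use a shared per-sample factor per module
per condition, giving the analytically known within-module correlation
$\lambda^2/(\lambda^2+\sigma^2)$ (≈ 0.92 at loading 1, noise 0.3) that
the MI and alignment recovery tests rely on. `simulate_ppin()` grows a
connected preferential-attachment graph with exactly $m(n-m)$ edges and a
heavy-tailed degree distribution; `simulate_drug_catalog()` samples
targets from the interactome with typed actions, including an
"unspecified" mass because real catalogs leave most actions untyped. All
generators are pure functions of (configuration, seed).

The defaults in `default_study_config()` — four stages of 6–8 samples,
120 genes, 2-log2-unit effects, noise 0.5, two batches offset by 0.6, a
20-gene shared module and a 20-gene stage-specific module — are desk-scale
stand-ins chosen to match the group sizes and effect magnitudes typical
of staged microarray series while keeping the full pipeline (including
all-pairs MI and permutation nulls) under a minute. The generators do
**not** emulate probe-level artifacts, platform-specific batch
signatures, heavy-tailed expression noise, correlated DE blocks beyond
the factor model, or realistic pharmacology; passing recovery tests shows
the estimators work when their assumptions hold, not that real staged
data satisfies those assumptions.

One behaviour of the factor model is worth knowing: with few samples per
group, a shared latent factor produces nonzero *sample-mean* differences
between groups for every module gene, so module genes can legitimately
reach significance in a DE contrast even without a planted shift. The DE
calibration tests therefore use configurations without modules.

## Numerical conventions and degenerate inputs

* All generator and analysis randomness is seeded; derived sub-seeds stay
  below $2^{31}$.
* KNN-MI tie jitter is uniform on $(0, 10^{-10})$, seeded by gene index.
* `hard_threshold`: the quantile is computed on strictly positive weights
  (type-7); `q = 0` retains all positive edges; an all-zero matrix warns
  and returns an empty network.
* Eigengap ties resolve to the smallest k; k-means restarts with derived
  sub-seeds up to 10 times if a cluster empties, then errors.
* A single-sample dataset passes through `quantile_normalize` unchanged
  with a warning; single-sample batches are centered but flagged.
* `separation`/`proximity_zscore` error on empty sets; nodes missing from
  the graph are named in the error.

## Known limitations

* Only pairwise network alignment and pairwise (two-group) contrasts are
  supported — the designs this analysis family actually uses.
* The all-pairs KNN-MI step is $O(p^2 N^2)$; it is comfortable at
  hundreds of genes (screen first with `top_variable_genes`) but not at
  whole-transcriptome scale.
* Batch correction is additive mean-centering only.
* z-score significance is read from its sign, not a multiplicity-corrected
  threshold; "effective" is a topological configuration, not a clinical
  claim.
* Proximity screening inherits the incompleteness of the interactome:
  drugs with sparse interaction coverage are silently conservative
  (fewer than two mapped targets excludes them).
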