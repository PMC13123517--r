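---
title: "Methods: co-occurrence networks and cross-feeding scores for SAG communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence networks and cross-feeding scores for SAG communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model overview

`sagnet` analyses communities of single amplified genomes (SAGs) sampled
from two contrasting treatments — here labelled *C-depleted* and
*C-enriched* soils. It covers four connected analyses:

1. **Genome features.** Quality filtering, completeness-corrected genome
   size, and the power-law relationship between coding-sequence (CDS)
   count and genome size.
2. **CAZyme function.** Binary carbohydrate-active-enzyme family profiles,
   Jaccard functional distances, their association with phylogenetic
   (patristic) distance, and per-family enrichment between treatments.
3. **Co-occurrence networks.** Compositionally aware correlation inference
   from abundance tables, thresholded networks partitioned into
   sub-communities, with null-model and rarefaction validation.
4. **Cross-feeding.** Aggregation of per-interaction metabolite exchange
   scores (SMETANA-style detailed output) into sub-community sum and
   size-normalized scores, metabolite-category profiles, PCA, and
   category-level group tests.

Every pipeline input can be generated synthetically with planted,
recoverable structure, so each estimator is validated against known truth
without any external download.

# Genome features

Completeness-corrected size is `assembly_length / (completeness / 100)`;
it is never smaller than the assembly. The quality filter keeps genomes
with completeness ≥ 50% and contamination ≤ 10% (both boundaries
inclusive; both thresholds are arguments). Unusually large genomes are
*flagged* at `Q3 + 3·IQR` of the estimated-size distribution rather than
removed — there is no principled universal cutoff, so removal sits behind
an explicit flag.

The scaling analysis fits one ordinary least-squares line
`log10(CDS) = a + b·log10(size)` pooled over both treatments. Pooling is
deliberate: residuals are only comparable between groups when they are
measured against a common expectation. Base-10 logs are used for
readability; any base yields the same residual comparisons. Group
comparisons of size, CDS, GC and residuals use the tie-corrected
Kruskal–Wallis test with Benjamini–Hochberg correction across the feature
family; percent differences are reported on group means,
`(mean_E − mean_D)/mean_D × 100`, with medians also available.

# CAZyme functional distances and enrichment

Profiles are binary per family (duplicate annotations collapse). The
Jaccard distance is `1 − |F_i ∩ F_j| / |F_i ∪ F_j|`. Two genomes with no
annotations are at distance 0 (identical emptiness); an empty against a
non-empty profile is at distance 1. Phylogenetic distance is the patristic
(branch-length path) distance; the tree metric was left open by the
source data conventions, and patristic is the standard choice when branch
lengths are available.

The phylogeny–function association is assessed per treatment by the
least-squares slope and r² of functional on phylogenetic distance over
genome pairs, with significance from a Mantel permutation test (999 label
permutations of one matrix; two-sided pseudo-p `(b+1)/(B+1)`, which can
never return 0). Pair-level regression p-values would be anticonservative
because pairs sharing a genome are dependent; the Mantel test is the
field-standard fix.

Per-family enrichment uses a two-sided Fisher exact test on the 2×2
present/absent × treatment table. For binary data a count-based
differential model adds assumptions without benefit, so the exact test is
used with a Haldane-corrected effect size
`log2fc = log2(((a+0.5)/(n1+1)) / ((c+0.5)/(n2+1)))`, which is finite for
all-or-none families. Families are flagged at `q ≤ 0.05` and
`|log2fc| ≥ 1`.

# Compositionally aware correlation (SparCC-type)

Relative abundances sum to one, so naive correlations are biased; the
estimator works on log-ratio variances instead. For fractions `x`, the
variation matrix is `t_ij = var(log(x_i/x_j))`. Under the identity
`t_ij = ω_i² + ω_j² − 2 r_ij ω_i ω_j` and the sparsity approximation
(most basis correlations ≈ 0), component variances solve the linear
system over row sums of T, and
`r_ij = (ω_i² + ω_j² − t_ij) / (2 ω_i ω_j)`.

Implementation choices (all exposed as arguments):

* +1 pseudocount; fractions drawn per resample from the row-wise
  Dirichlet posterior; 20 resamples; element-wise median, clipped to
  \[−1, 1\].
* the strongest-correlated pair is iteratively removed from the variance
  system while max |r| > 0.1, at most 10 rounds (strong pairs violate the
  sparsity approximation); the pairwise identity always uses the full T.
* p-values permute each taxon's counts independently across samples and
  re-run the full estimator; two-sided pseudo-p `(b+1)/(B+1)` with 999
  permutations by default.
* basis variances are floored at 1e−12 before taking square roots; an
  exclusion that would empty a row of the system stops the loop instead
  of making it singular.

The resample/permutation core is implemented in C++ (RcppArmadillo) and
draws all randomness from R's RNG, so a single `set.seed` reproduces
every estimate bit-for-bit. With ≥ 4 taxa the system is solvable; all-zero
taxa are dropped first.

Edges are kept at `|r| > 0.6` and `p < 0.05` (both strict), signed r as
weight. The network's node set is the taxa incident to at least one
retained edge — node counts in the motivating study differ from its group
sample sizes, so nodes are not assumed to be "all genomes".

# Sub-communities, null models, rarefaction

Modules come from greedy modularity maximization on |r| weights
(agglomerative, deterministic); each module is a *sub-community* whose
size is its node count. Modularity Q uses the same weights.

The null model for Q matches **both** node and edge counts (Erdős–Rényi
G(n, m)): modularity depends strongly on density, so matching nodes alone
would make the standardized effect size
`SES = (Q_obs − mean_null)/sd_null` uninterpretable. Each null graph is
partitioned by the same algorithm. The empirical p is
`(#{Q_null ≥ Q_obs} + 1)/(N + 1)`; a degenerate null (sd 0) is flagged
rather than divided by.

The rarefaction test draws `k` taxa per treatment per iteration (default
18), re-infers the network with identical parameters, and records density.
Density here is computed over the *k rarefied taxa*, `2m/(k(k−1))`: the
incident-node convention would assign density 1.0 to any one-edge network
and so reward spurious single edges in the sparser group; rarefying to a
fixed genome count is precisely what makes a fixed denominator
meaningful. The group difference in mean density is tested by two-sided
permutation of group labels over the pooled per-iteration densities.

# Cross-feeding scores and categories

Each detailed exchange record is one (community, receiver, donor,
metabolite) with a score in \[0, 1\] and optional components satisfying
`scs·mus·mps = smetana` (checked at 1e−6 on input). The sub-community
**sum score** adds scores over *all* detailed rows — no prior collapsing
per pair, which is the natural granularity of the detailed output — and
the **size-normalized score** divides by member count, so
`normalized × size = sum` holds exactly. A community with no records
scores a defined zero.

Metabolite categories come from an editable TSV shipped with the package
(amino acids, aromatic compounds, B-vitamins, oligopeptides,
sugars/phosphosugars, nucleobases, other) keyed on BiGG-style
identifiers; unmapped metabolites are pooled into `other`, so category
row sums reproduce sum scores. The category matrix is column-standardized
(correlation PCA) so high-magnitude categories do not dominate; PCA rows
are sub-communities. Contributions per dimension are squared loadings
normalized to 100%.

Category group tests are Kruskal–Wallis per category with
`log2fc = log2((mean_E + ε)/(mean_D + ε))`, `ε = 0.5 × min positive
score`; the fold-change orientation is fixed by sorted (or canonical)
group labels, so swapping group memberships negates it exactly.
Categories observed in only one group are flagged *exclusive* rather than
tested — a rank test against all-zeros answers a different question.

# Synthetic-data generators

The generators define the conditions every recovery test runs under; they
are first-class, tested code.

* **Catalog**: 2×30 genomes by default; true sizes log-normal (C-depleted
  mean 3.5 Mb; C-enriched multiplied by 1.18, matching an 18% size
  difference), `size_sd_log = 0.35` — a catalog spanning roughly 1.5–10 Mb
  as in real soil collections; a narrower spread would leave the scaling
  slope weakly identified. CDS follows
  `round(10^(−2.38 + 0.9·log10(size) + ε))`, ε ~ N(0, 0.05²), i.e. ~3,600
  genes on a 4 Mb genome. Completeness ~ U(40, 100)% and contamination ~
  U(0, 15)% deliberately straddle the QC thresholds. GC is Gaussian per
  group (0.62 vs 0.57, a 9% relative difference). The tree is an
  ultrametric pure-birth simulation.
* **CAZyme matrix**: each family evolves on the tree as a two-state
  Markov process (default gain 0.3 / loss 0.7, stationary presence 0.3),
  inducing genuine phylogeny–function correlation; enriched families
  redraw tips of the target group at odds multiplied by the configured
  factor, which is also what makes enrichment detectable over the
  phylogenetic background.
* **Abundance table**: basis abundances are multivariate log-normal
  (σ_log = 1, heterogeneous per-taxon means) with block-diagonal
  correlation; fractions are multinomially sampled at depth 50,000 over
  40 samples. Multinomial (not Dirichlet-multinomial) sampling keeps the
  recovery test interpretable; overdispersion can be emulated by raising
  σ_log. Within-block pairs are returned as planted truth.
* **Exchange table**: per ordered pair and metabolite, rows appear with
  probability 0.25; scores are Beta with concentration 10 and mean 0.12
  in C-depleted sub-communities, shifted per category by the planted
  log2 fold changes (defaults 1.42 for amino acids, 0.76 for aromatic
  compounds); B-vitamins are emitted only in C-enriched communities.
  Components are `smetana^a` with Dirichlet exponents summing to 1, so
  the product identity is exact by construction.

What the generators do **not** emulate: taxonomic structure in abundances,
sequencing error, uneven sample depths, overdispersion beyond log-normal
basis noise, non-ultrametric trees, and any coupling between CAZyme
content and exchange scores. Passing recovery tests therefore demonstrate
estimator correctness under the stated model, not robustness to every
property of real data.

# Problem sizes and numerical conventions

Test and demo sizes are chosen to exercise each method at meaningful power
while staying desk-scale: planted-edge recovery at 30 taxa × 40 samples,
depth 5×10⁴; SES calibration over 100 random graphs with 200 nulls each;
rarefaction calibration over 50 trials of 100 iterations (null at 3
resamples/39 permutations — calibration does not depend on power — and
planted-block detection at 5 resamples/99 permutations); category
recovery at 50 sub-communities per group. The shipped demo configuration
(`inst/extdata/demo_config.yaml`) runs the full pipeline in a few seconds
and is deterministic given its seed.

Conventions worth restating: permutation p-values are always
`(b+1)/(B+1)`; correlations are clipped to \[−1, 1\]; degenerate cases
(constant distances, zero null sd, all-zero profiles) are flagged or
raised as typed errors (`sagnet_config_error`, `sagnet_input_error`,
`sagnet_format_error`, `sagnet_domain_error`, `sagnet_degenerate_error`)
rather than returning misleading numbers.

# Known limitations

* The sparsity approximation behind the basis solve degrades when many
  taxa are strongly correlated; the exclusion loop mitigates but does not
  remove this.
* Permutation p-values at small B are coarse (min `1/(B+1)`); edge
  retention at `p < 0.05` needs B ≥ 39.
* Greedy modularity maximization is deterministic but not optimal; SES is
  comparable across graphs only because observed and null graphs use the
  same algorithm.
* The category vocabulary is a compact stand-in, editable by the user;
  real exchange tables will contain many metabolites that fall into
  `other`.
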