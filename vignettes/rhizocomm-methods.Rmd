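---
title: "Methods: growth-linked rhizosphere community analysis in rhizocomm"
author: "rhizocomm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth-linked rhizosphere community analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizocomm)
```

# Scope and model

`rhizocomm` links plant growth performance to rhizosphere microbiome
structure starting from a finished amplicon feature table (samples ×
ASVs), a rooted phylogeny with branch lengths, a ranked taxonomy, sample
metadata (cultivar, replicate) and a cultivar-level growth-trait table.
The workflow is: post-denoising filters and normalization → growth-based
clustering of cultivars → alpha/beta diversity and factor testing →
null-model partitioning of community assembly processes → compositional
genus-level co-occurrence networks compared across growth clusters. A
seeded synthetic-data generator reproduces the study design (by default
cultivars × 3 replicates, phylogeny-structured taxa, three latent
growth clusters, five controllable assembly regimes) so that every stage
can be validated against planted ground truth.

# Preprocessing

Three filters are applied in a fixed order, matching the upstream
workflow: singleton removal (total count across all samples exactly 1),
the two-of-three replicate rule, then total-sum scaling (TSS) to
relative abundances. Each filter is idempotent and never drops samples.

The replicate rule is read *existentially*: a taxon is kept if at least
one cultivar shows it in ≥ 2 of that cultivar's replicates. A universal
reading (required in every cultivar) would empty any realistic table, and
the downstream analyses never split the table by cultivar.

The core microbiome qualifies a taxon within a group when its relative
abundance is **strictly greater** than 0.01% in **at least** 80% of the
group's samples; prevalence uses ≥, abundance uses >, following the
stated rule exactly. Qualifying taxa are partitioned into Venn regions
(each taxon assigned to the exact combination of groups in which it
qualifies), and each region is annotated with the proportion of reads its
taxa carry, averaged over all samples of the compared groups.

# Growth clustering

Traits (shoot fresh/dry weight, leaf count, tuber weight and number; one
row per cultivar, replicate means) are z-scored per trait (n − 1
denominator). Two clusterings are run with Euclidean distance: k-means
(best of 25 seeded restarts) and agglomerative ward.D2 linkage. Clusters
are then ranked `high`/`medium`/`low` by the mean of row-summed z-scores;
exact ties go to the cluster with the heavier mean tuber weight.

Two criteria are available for choosing k:

* **WSS elbow (default).** The total within-cluster sum of squares is
  computed for k = 1..k_max and the elbow is the k whose point on the
  (normalised) curve lies farthest from the chord joining its endpoints.
  We use this geometric definition rather than the maximum second
  difference because performance clusters lie along a gradient (high →
  medium → low are ordered in every trait); on such data the curvature
  of the WSS curve is always largest at k = 2 even when three clusters
  are planted, while the distance-to-chord elbow recovers the planted k.
* **Silhouette.** Mean silhouette width maximised over k = 2..k_max; a
  best width below 0.5 triggers a "weak structure" warning, following the
  Kaufman–Rousseeuw interpretation scale.

Group separation is tested by ANOSIM on Euclidean trait distances (the
same metric as the clustering), with the permutation p-value estimated as
(count + 1)/(n_perm + 1) so p = 0 is unattainable.

# Diversity

Alpha diversity reports observed richness, Shannon entropy (nats) and
Simpson's index. Because "Simpson index" is used for both orientations in
the literature, the dominance form λ = Σ p² and its complement 1 − λ are
both returned; within-sample proportions are always recomputed
internally, so the metrics are invariant to prior normalization.

Beta diversity uses normalized weighted UniFrac: for samples A and B,
`sum_i b_i |A_i − B_i| / sum_i b_i (A_i + B_i)` over all branches, where
`b_i` is the branch length and `A_i` the relative abundance descending
from the branch. The implementation accumulates per-branch abundances in
one postorder pass; the test suite validates it branch-by-branch against
an independent enumeration oracle. Ordination is principal coordinates
analysis with Gower centring; negative eigenvalues are reported, never
silently dropped.

Factor effects on the distance matrix are tested with one-factor
PERMANOVA models (999 permutations by default), one per factor, so each
R² is order-independent — matching the way factor-wise variance
contributions are usually tabulated. Differential abundance between
groups uses two-sided Wilcoxon rank-sum tests for every group pair and
feature, with Benjamini–Hochberg adjustment across the entire family.

# Community assembly null models

For each sample pair, the abundance-weighted β-mean-nearest-taxon
distance (βMNTD) is the average patristic distance from each taxon to its
closest relative in the other community; shared taxa contribute zero (the
conspecific is its own nearest taxon). βNTI is the z-score of the
observed βMNTD against a null distribution generated by random shuffles
of the taxa across the phylogeny's tips — one shared permutation per
iteration, abundances untouched — so βNTI is invariant to uniform
rescaling of branch lengths. Pairs whose null distribution has zero
spread (e.g. on a star phylogeny, where shuffling cannot change any
distance) are flagged unclassifiable rather than silently set to 0.

RCbray preserves each sample's observed richness and total read count:
null species are drawn without replacement with probability proportional
to occurrence frequency, reads are then allocated multinomially with
probability proportional to mean relative abundance, and the observed
Bray–Curtis value is located in the null distribution and rescaled to
[−1, 1]. RCbray operates on counts (before TSS) because the null fixes
observed totals.

Classification follows the standard two-stage thresholds: βNTI > 2 →
heterogeneous selection; βNTI < −2 → homogeneous selection; otherwise
RCbray > 0.95 → dispersal limitation, RCbray < −0.95 → homogenizing
dispersal, else undominated. Boundary values (|βNTI| = 2, |RCbray| =
0.95) fall on the stochastic/undominated side. The default null count is
1000; the validation experiments below use 199–500 so they run at desk
scale. Per-group summaries use within-group pairs (matching per-cluster
assembly panels); an all-pairs option exists for whole-table analyses.

# Co-occurrence networks

Counts are agglomerated at the genus level — taxa unclassified at genus
are pooled as `U. <deepest classified rank>` so reads are conserved —
and clr-transformed (`ln(x + 1)` centred per sample). Taxa never observed
in a group are removed before the clr: an all-zero column's constant log
value would otherwise track the row mean and generate artefactual edges.

An edge is kept only if all enabled criteria hold: |Pearson r| ≥ 0.3,
two-sided t-test p ≤ α (0.0001 for the bacterial workflow, 0.05 for
fungal), and local FDR ≤ 0.2. The local FDR uses a two-component
empirical-null mixture on Fisher-z correlations (null centre and spread
by median/MAD central matching, marginal density by kernel smoothing);
with fewer than 200 tests the estimate is unstable, so the function falls
back to Benjamini–Hochberg q-values and says so. The conjunction is the
strictest reading of a pipeline that names all three criteria; each is
individually toggleable, and relaxing any one criterion can only add
edges (a tested monotonicity property).

Modules come from greedy modularity maximisation (Clauset–Newman–Moore)
on absolute edge weights; Q ≥ 0.4 flags a modular topology. Note that the
greedy agglomeration is a heuristic: on small unstructured graphs it can
return a partition below the global optimum, so exact-agreement checks
against exhaustive search are meaningful only on graphs with actual
modular structure (the validation uses planted two-block graphs, and
separately verifies the Q value of whatever partition is returned against
the definitional formula).

Hubs are nodes whose eigenvector centrality (absolute-weight adjacency of
the largest connected component) exceeds the 95% empirical quantile
strictly, with a 1e-9 numeric guard so exact ties — e.g. regular graphs,
where every node is equally central — yield an empty hub set instead of
promoting nodes through eigensolver jitter.

Topology metrics per network: component count over the **full genus
universe** (isolated genera are singleton components), mean local
clustering over nodes of degree ≥ 2, modularity, positive-edge
percentage, edge density over the universe, robustness, average path
length over reachable pairs, and module count. Robustness is natural
connectivity — `ln` of the mean exponential of adjacency eigenvalues —
computed over the full universe (isolated nodes contribute zero
eigenvalues) and normalised by N − ln N. Computing it over the universe
rather than over connected nodes only keeps networks with different
connected sizes comparable: a small clique would otherwise outscore a
larger, structurally richer network, and the magnitudes produced this way
(a few 10⁻³ for hundreds of genera) match how such tables are reported.
The raw unnormalised value is also returned.

# The synthetic-data generator

No generative model is prescribed upstream, so the generator adopts the
minimal model under which the βNTI null is informative: a
**niche-filtering multinomial sampler**. A pure-birth phylogeny carries a
trait optimum per taxon evolved by Brownian motion; each sample has an
environmental value; sampling weights are metacommunity abundance
(lognormal(0, 1), drawn once) damped by `exp(−(optimum − env)² /
(2 σ²))`; counts are multinomial at the requested depth. Per-sample
occupancy subsets (each taxon available to a sample with probability
drawn once from U(0.35, 0.95)) emulate dispersal and drift. The five
regimes:

* **neutral** — occupancy subsets and metacommunity weights only.
* **homogeneous selection** — one shared env (the median optimum) with a
  narrow filter; communities converge on the same clades.
* **heterogeneous selection** — env values on an even grid across the
  5–95% optimum quantiles, one per sample; communities diverge.
* **dispersal limitation** — disjoint taxon pools per group of samples
  (group size 4 by default, overlap tunable).
* **homogenizing dispersal** — a common multinomial backbone of
  `dispersal_mix × depth` reads literally shared by all samples (drawn
  from a restricted common pool covering ~60% of taxa) plus
  sample-specific drift reads. Mixing *weights* toward a pooled mean
  cannot produce the RCbray < −0.95 signature, because the Raup–Crick
  null estimates occurrence and abundance from the same table: identical
  expected compositions give RC ≈ 0. Sharing realised reads puts the
  observed Bray–Curtis below the null's multinomial noise floor, which is
  precisely the "more similar than expected" signal the classifier
  detects.

Brownian motion at a constant rate on a pure-birth tree leaves sibling
optima far apart relative to a strong filter (tip divergence is dominated
by deep splits only on the variance scale, not locally), so a narrow
filter selects a phylogenetically scattered slice of taxa and βNTI stays
near 0 even under strong selection. `simulate_trait_optima(rate_decay >
0)` therefore offers an early-burst variant — the Brownian rate decays
exponentially with time from the root — under which niche divergence
concentrates in deep splits and clades are internally conserved, the
premise of nearest-taxon-distance null models. The recovery experiments
use `rate_decay = 2`.

Growth traits are drawn per cultivar around one of three cluster means
(greenhouse-scale potato values; see `default_cluster_means()`), with
`noise_sd` expressed in units of each trait's between-cluster spread
(default 0.15, i.e. clusters separated by ~7 within-cluster standard
deviations — crisply separated, as observed growth clusters are).
Cluster sizes are balanced up to rounding. Taxonomies are built by
cutting the phylogeny's cophenetic dendrogram into nested clades
(domain → genus), with a tunable fraction of taxa left unclassified at
genus (`NA`, later pooled as `U. <rank>`).

What the generator deliberately does **not** emulate: sequencing error,
chimeras, PCR and primer bias, compositional library-size variation
(depth is constant), contaminants, temporal dynamics, and
bacteria/fungi-specific marker differences. Passing the validation
experiments therefore demonstrates that the *statistical machinery* is
correct and calibrated on data satisfying its assumptions — not that any
particular real dataset will show the same effect sizes.

# Validation experiments and problem sizes

The acceptance tests and `scripts/acceptance.R` run the same seven
experiments; sizes are chosen to exercise the study's scale while keeping
a full run in a few minutes:

1. **Null calibration** — neutral tables of 30 samples × 150 taxa at
   depth 5000, 500 null shuffles, 10 seeds; the fraction of pairs with
   |βNTI| > 2 averages well under 0.10.
2. **Regime recovery** — 10 samples × 500 taxa at depth 5000 per regime
   (500 taxa is a modest richness for soil and gives the nearest-taxon
   null room to discriminate), early-burst optima (`rate_decay = 2`),
   `selection_sd = 0.05` on optima of sd 1, 199 nulls, 10 seeds per
   regime; each regime must be the modal classification in ≥ 8/10 runs.
3. **Oracle equivalence** — 50 random small instances per primitive
   (patristic distances, weighted UniFrac, βMNTD, average path length,
   modularity, eigenvector hubs) against independent brute-force
   implementations.
4. **Statistical calibration** — 500 null simulations for PERMANOVA and
   ANOSIM (empirical type-I error within 0.05 ± 0.02 at α = 0.05) and
   600 replicates of a 200-feature null panel for Wilcoxon + BH
   (realised FDR ≤ 0.07).
5. **Growth recovery** — 51 cultivars, 3 planted clusters, noise 0.15;
   k selection must return 3 and k-means reach ARI ≥ 0.9 in ≥ 9/10
   seeds, with Ward agreeing at ARI = 1.
6. **Network discrimination** — two groups sharing one correlated genus
   block while only one carries a second block (sign-alternating
   loadings so blocks stay out of the clr row mean); the blockless group
   must show strictly fewer nodes, fewer edges and lower robustness, and
   modules must recover the planted blocks (ARI ≥ 0.8).
7. **Filter chain** — all 2⁶ presence patterns of a taxon across 2
   cultivars × 3 replicates against exhaustive evaluation of the rules.

# Numerical choices and degenerate inputs

* Permutation p-values always use (count + 1)/(n_perm + 1).
* βNTI needs ≥ 100 nulls; degenerate pairs (null sd < 1e-12) are `NA`
  and counted separately by `summarize_fractions()`, whose five process
  fractions always sum to 1 over classified pairs.
* RCbray tie handling uses a 1e-12 tolerance on Bray–Curtis equality.
* TSS and alpha diversity refuse empty samples by name; UniFrac and
  βMNTD refuse taxa missing from the tree by name.
* The clr pseudocount defaults to 1; zero-variance genera are excluded
  from correlation testing with a warning.
* Hub quantile comparisons are strict with a 1e-9 guard.
* All randomness flows from one user seed through a fixed splitting rule
  (each stage derives a 32-bit sub-seed from the seed and a stage
  index), so every simulator and permutation test is bit-reproducible.

# Known limitations

* The local FDR's central-matching estimator assumes the bulk of
  correlations is null; in tiny or strongly structured panels it falls
  back to BH.
* Greedy modularity is a heuristic (see above); on large networks the
  partition is good but not certified optimal.
* The generator's regimes are idealised endpoints; real communities mix
  processes within a single pair of samples, and the classifier reports
  only the dominant signal.
* PERMANOVA is run factor-by-factor; confounded factors (e.g. cultivar
  and growth cluster, which is a function of cultivar) each absorb
  overlapping variance, as in the factor-wise reporting convention this
  mirrors.
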