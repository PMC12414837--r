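---
title: "Methods: gene and isoform-ratio co-expression network rewiring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene and isoform-ratio co-expression network rewiring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(isorewire)
```

## The problem

Differential expression compares features one at a time and misses changes in
how genes are *co-regulated*. `isorewire` compares two sample groups (we call
them affected and unaffected throughout) by building one co-expression network
per group and asking where the wiring differs. Two kinds of features enter
each network:

* **TE (total expression) nodes** — a gene's corrected log2-CPM expression;
* **IR (isoform ratio) nodes** — one transcript's corrected logCPM divided by
  its parent gene's, a per-sample measure of relative isoform usage.

Mixing the two modalities in a single network lets isoform-usage co-regulation
("splicing wiring") appear alongside, and be compared with, ordinary
expression wiring. Transcript usage can shift while gene totals stay flat, so
IR nodes carry signal that gene-level networks cannot.

## Preprocessing

The preprocessing order is fixed and mirrors common RNA-seq practice:

1. **Filtering** — keep features with a count of at least `min_count` (10) in
   at least `ceil(min_frac * n)` samples (`min_frac` = 0.95, boundary
   inclusive).
2. **logCPM** — `log2((count + 0.5) / (library_size + 1) * 1e6)`. The 0.5
   prior count and `+1` library offset follow the common logCPM convention.
3. **Residualization** — per feature, a *single joint* OLS fit on an intercept
   plus all listed covariates (batch, sex, age, BMI, five cell-type PCs by
   default); the fitted covariate contribution is subtracted while the
   intercept is kept, so values stay on the logCPM scale. A joint fit is
   order-independent and equivalent in expectation to removing covariates
   sequentially; the group label is never allowed into the design, so
   group-associated signal is untouched by construction. Rank-deficient
   designs are an error that names the collinear columns.
4. **Negative pruning** — subtraction can push low-expressed features below
   zero; any feature with a negative corrected value is dropped entirely.
5. **Isoform ratios** — IR(t, s) = tx(t, s) / gene(g(t), s) on the corrected
   logCPM matrices. We deliberately use the corrected *logCPM* gene values as
   the denominator (both matrices live on that scale); a 0/0 entry is imputed
   with the transcript's mean ratio over the samples where it is defined, and
   a transcript undefined everywhere is dropped with a warning. A zero
   denominator against a non-zero numerator indicates inconsistent inputs and
   is an error.
6. **Outlier removal** — PCA is run separately on the gene matrix and the IR
   matrix (samples as observations, features centered); a sample deviating
   from the mean by more than `sd_mult` (2) standard deviations on PC1 or PC2
   of *either* matrix is removed. The union convention is the permissive
   reading of "outlier on either component of either view"; with four
   criteria at 2 SD each, expect roughly 10–20% of clean Gaussian samples to
   be flagged.

Differential expression uses all samples; network inference uses the
outlier-pruned set. IR features with (near-)zero variance (e.g. single-isoform
genes, whose ratio is identically 1) are dropped before inference because
mutual information is undefined for constants.

## Moderated differential expression

`moderated_de()` fits, per feature, expression on intercept + group, so the
log fold change is exactly the affected-minus-unaffected difference of group
means. Residual variances are shrunk by empirical Bayes: with residual
degrees of freedom $d$ and per-feature variances $s_g^2$, the prior
$(d_0, s_0^2)$ is estimated by method-of-moments matching on
$e_g = \log s_g^2 - \psi(d/2) + \log(d/2)$, solving
$\psi'(d_0/2) = \widehat{\mathrm{Var}}(e) - \psi'(d/2)$ with a Newton
trigamma inverse. With `trend = TRUE` (default) the prior mean is a lowess
function of average expression, so low- and high-abundance features get their
own prior scale. The moderated t uses the posterior variance
$(d_0 s_0^2 + d s_g^2)/(d_0 + d)$ on $d_0 + d$ degrees of freedom; at
`prior_df = 0` it reduces exactly to the ordinary two-sample t. This is the
standard shrinkage construction for logCPM-scale linear models, implemented
here so the package is self-contained; the test suite cross-checks it against
an independent reference implementation on simulated fixtures.

Multiple testing uses our own Benjamini–Hochberg step-up (`bh_adjust()`),
tested for exact agreement with the base-R reference on random p-vectors.
**Isoform-specific DE** is the set of transcripts significant at the FDR
threshold whose parent gene is not (or was filtered out at the gene level) —
the "DTE without DGE" pattern — plus a directional overlap partition of
gene-level-only / both / transcript-level-only calls.

## Network inference

`estimate_mi()` offers two estimators, both in nats:

* **Gaussian copula** (default): each feature is rank-transformed to normal
  scores `qnorm((rank - 0.5)/n)` and MI is the bivariate-normal closed form
  $-\tfrac12\ln(1-\rho^2)$ on the score correlation. It is closed-form,
  robust to monotone marginal distortions, and accurate at the cohort sizes
  the pipeline targets; it captures monotone dependence only.
* **Binned**: equal-frequency binning with plug-in MI and a Miller–Madow
  bias correction, clamped at zero. The default bin count is the cube-root
  rule `floor(n^(1/3))`: with `sqrt(n)` bins the joint table at n ≈ 10³ has
  nearly as many cells as samples and the Miller–Madow correction leaves a
  residual bias of ~0.2 nats, whereas cube-root binning keeps the residual
  near 0.01 nats. The binned estimator can detect non-monotone dependence
  but is noisier.

`prune_dpi()` applies the data processing inequality: in every triangle
(i, j, k), edge (i, j) is marked when
$MI_{ij} < \min(MI_{ik}, MI_{jk}) - \varepsilon$. All marks are computed on
the input graph and applied simultaneously, so the result is independent of
edge order (some ARACNE implementations are order-dependent). The default
tolerance is $\varepsilon = 0$. Note that an edge that is the maximum of one
triangle can still be removed through a different triangle; the guarantee is
per triangle, and the suite checks the implementation against an exhaustive
brute-force triangle oracle. The triangle scan is an O(E·V) C++ kernel on a
dense adjacency, which keeps ~1,000-node problems at a few seconds.

`infer_network()` stacks the TE and IR features of one group, estimates MI,
keeps positive-MI pairs, prunes with the DPI, and finally removes every edge
whose endpoints belong to the same gene (a gene with its own transcript, or
sibling transcripts), since those are trivially coupled through the ratio
construction. Isolated nodes are kept so node counts remain reportable. No
permutation-based MI significance filter is applied; the only confidence
filter is the median threshold below.

`threshold_pair()` computes, per edge type (TE-TE, TE-IR, IR-IR), the median
MI of the *reference* (affected) network's edges and keeps edges with
`mi >= threshold` in both networks. The comparison is inclusive so ties are
retained; on continuous weights the reference keeps 45–55% of its edges per
type. Thresholding on the affected network's medians makes the two networks
comparable when the groups have unequal sample sizes (the smaller group's MI
estimates are noisier, which otherwise inflates its edge count).

## Differential network analysis

All definitions are inclusive at their boundaries:

* **Hub** — degree ≥ k (default 10) in a thresholded network; **common
  hubs** are hubs of both networks.
* **Unique edge** — an edge of one thresholded network *absent from the
  unthresholded version* of the other network; requiring absence before
  thresholding makes "unique" robust to edges that merely fell below the
  other network's threshold. Edges incident to common hubs partition into
  unique / shared (present in both thresholded networks) / attenuated
  (present in the other network only unthresholded); the three sets are
  disjoint and exhaustive, and the unique percentage is
  `100 * unique / (unique + shared + attenuated)`. Reporting the attenuated
  class separately makes either convention (with or without it) reproducible.
* **Master hub** — degree ≥ k in the focal thresholded network and at least
  `min_fold` (default 2, inclusive: "a minimum fold of two" is read as ≥ 2,
  and exact-boundary folds are flagged in a `boundary` column) times its
  degree in the *unthresholded* other network. A node absent from the other
  network has infinite fold — absence is the strongest rewiring signal — and
  qualifies on degree alone. Tables are sorted by focal degree with
  deterministic ties so "top master hubs" is well defined.
* **Modality subnetworks** — TE-TE edges as gene pairs versus IR-IR edges
  mapped to parent-gene pairs; an edge is unique to its modality when its
  gene pair does not occur in the other modality's set. Integer percentages
  use `round` by default with a `floor` option, since truncated percentages
  appear in published reports.
* **Neighborhoods** — 1- or 2-hop BFS from a seed set, seeds included by
  default.

## Validation by surrogate graphs

Whether two inferred networks differ *beyond noise* is quantified by a
simulate–embed–classify loop (`separation_score()`):

1. **Perturbation** (`perturb_graph()`): each edge is kept independently with
   probability `retention` (default 0.9) and removed edges are replaced —
   same expected count — by edges sampled with probability proportional to
   the product of original endpoint degrees, rejecting self loops, duplicates
   and same-gene pairs. This is a degree-biased edge-resampling surrogate: it
   preserves the node set and approximate degree structure while injecting
   topology noise. We use it in place of a trained generative graph model:
   the validation logic (simulate → embed → reduce → classify) is what
   matters, and a closed-form perturbation keeps the stage fast, dependency
   free, and exactly reproducible.
2. **Embedding** (`wl_embed()`): Weisfeiler–Lehman label refinement from node
   modality labels for 3 rounds; every label observed at every round is
   hashed by a fixed, seed-independent 31-bit polynomial hash into one of
   `dim` = 128 buckets, and bucket counts are normalized to term
   frequencies. Isomorphic graphs (with matching modality labels) embed
   identically. Hashed WL subtree counts are the same feature family that
   neural whole-graph embedders consume; using them directly avoids training
   an embedding model while preserving what the features measure.
3. **Classification**: PCA to 10 components, then an L2-penalized logistic
   regression (fixed λ = 1, Newton iterations — immune to perfect-separation
   divergence) on stratified 80/20 train/test splits, repeated 10 times; the
   mean test accuracy is reported together with 2-D PCA coordinates for
   plotting. 100 surrogates per network is the default ensemble.

Identical input networks give chance-level accuracy (the suite checks
0.35–0.65 at 100+100 graphs); strongly rewired synthetic pairs reach ≥ 0.92.

## The synthetic-data generator

`sim_config()` + `build_ground_truth()` + `simulate_counts()` define the
study conditions every test runs under. Defaults: 300 genes with 2–3
isoforms each, 9 modules, 150 affected / 75 unaffected samples,
`rewire_fraction` 0.5, 5 planted master hubs at fold 2.5, 20 usage-switch
genes (logit shift 1.5), 20 DE genes (|log2FC| = 1), NB size 30, library
sizes 0.8–1.2 million, and batch/sex/age/BMI/cell-PC covariates with small
log-scale effects.

Design choices that matter, and why:

* **Star modules with near-noiseless hubs.** Each module is a hub-and-spokes
  star; genes load on a latent module factor through a log link (hubs at
  loading 1 with residual SD 0.15, spokes at 0.45 with residual SD 0.6).
  Triangle-based pruning can only recover a star if hub–spoke correlation
  clearly exceeds spoke–spoke correlation; with a near-noiseless hub the
  spoke–spoke correlation is roughly the *square* of hub–spoke, which gives
  the DPI the margin it needs. With comparable hub and spoke noise the
  module degenerates into an equicorrelated block and pruning keeps an
  arbitrary tree instead of the star.
* **Variance-preserving rewiring.** A rewired edge means the spoke loads on
  the module factor in one group only; in the other group the lost factor
  variance is replaced by idiosyncratic noise of the same size. Marginal
  distributions are then identical across groups, so rewiring changes
  co-expression *only* — no compositional or mean-shift differential
  expression leaks in. (Without this, group-specific loadings shift expected
  count shares and create spurious DE.)
* **Planted master hubs** get a higher spoke loading (0.85) and keep all
  their spokes in the affected group but only `floor(degree/fold)` of them
  in the unaffected group, so the recorded partner-count fold is always
  ≥ the configured 2.5. The higher loading both lifts planted edges above
  the affected network's median-MI threshold and lets the hub's retained
  unaffected-group edges dominate (and thus DPI-remove) chance edges that
  would otherwise inflate the unaffected-degree denominator.
* **Counts**: genes are negative binomial around library-size-scaled
  softmax shares; transcripts are a Dirichlet–multinomial split of the
  gene's count (concentration 30), so transcript counts sum *exactly* to the
  gene count in every sample. Usage-switch genes shift the first isoform's
  logit in the affected group only — transcript-level DE with gene totals
  untouched by construction. Isoform usage couples to a per-module splicing
  factor correlated 0.35 with the expression factor, which creates IR-IR
  modules and a moderate number of TE-IR edges.
* **NB size 30**: the latent factor layer already carries the correlated
  biological variance (residual SD 0.6 on the natural-log scale ≈ 60% CV),
  so the NB layer models residual counting/technical noise; total per-gene
  variability lands near what blood RNA-seq cohorts show. Covariate effect
  sizes are free parameters (no external estimates exist for them); defaults
  are small but comfortably detectable by the residualization step.

What the generator does *not* emulate: read-level sampling, GC and positional
bias, correlated covariates (e.g. age–BMI), cell-type mixtures driving
expression directly, heavy-tailed library sizes, or annotation errors in the
transcript-gene map. Passing tests therefore demonstrate that the pipeline
recovers planted structure under controlled, favourable noise — not that it
would do so on any given real cohort.

## Numerical conventions and degenerate inputs

* Seeds: every stochastic operation takes an explicit seed; identical
  (config, seed) pairs give byte-identical outputs, and every written
  artifact carries the config digest and seed in a header.
* Ties: thresholds and fold rules are inclusive (≥); master-hub tables break
  degree ties by node id; the WL hash is fixed and seed-independent.
* Constant features are an error in `estimate_mi()` (named in the message);
  the pipeline drops zero-variance IR features with a message beforehand.
* Empty edge types in the reference network make the per-type threshold
  undefined and raise an error rather than silently passing everything.
* Groups below 20 samples trigger a reduced-inference-power warning, not an
  error.

## Problem sizes

The shipped defaults (300 genes, ~750 transcripts, 225 samples) are
desk-scale: full network inference takes a few seconds per group and the
complete pipeline with validation runs in well under a minute; the test
suite, including the end-to-end recovery and calibration experiments, runs
in a few minutes. Cohort-scale runs (10⁴ features) are configuration-only
but the dense O(E·V) DPI scan grows accordingly.

## Known limitations

* The Gaussian-copula estimator sees monotone dependence only; the binned
  estimator is offered for non-monotone signals but needs larger n.
* The DPI removes chains, but genuinely dense co-expression (cliques of
  near-equal MI) is reduced to an arbitrary subset of edges — module
  *membership* is better read from the thresholded neighborhood than from
  individual surviving edges.
* Master-hub folds compare a thresholded degree with an unthresholded one;
  a handful of chance edges in the unthresholded network can push a true
  master hub below the fold, which bounds recall at moderate sample sizes.
* The degree-biased perturbation preserves degree structure only in
  expectation; it does not preserve triangle counts or assortativity the way
  a trained generative model can.
* Spectral or modularity-based community detection is out of scope; modality
  (TE vs IR) dominates any naive clustering of the combined network.
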