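# isorewire

Integrative gene + isoform-ratio co-expression network analysis for two-group
RNA-seq studies.

## What it is for

Case–control transcriptomics usually stops at differential expression, which
tests features one at a time. `isorewire` instead asks *where the wiring
differs*: it builds one mutual-information co-expression network per group and
compares their topology. Each network mixes two node modalities:

* **TE (total expression)** — a gene's corrected log2-CPM expression;
* **IR (isoform ratio)** — one transcript's corrected logCPM divided by its
  parent gene's, capturing relative isoform usage.

Because transcript usage can shift while the gene total stays flat, IR nodes
expose splicing-level co-regulation that gene-level networks miss. The
intended users are statistical-genomics analysts with gene- and
transcript-level count matrices for two groups (e.g. affected vs unaffected
cohorts) who want hub-level rewiring calls rather than per-gene p-values.

## The method in brief

1. **Preprocess**: filter features (count ≥ 10 in ≥ 95% of samples), logCPM
   (`log2((c + 0.5)/(N + 1)·10⁶)`), joint OLS residualization of nuisance
   covariates, removal of features with negative corrected values, isoform
   ratios with 0/0 mean-imputation, and PCA outlier removal (|score| > 2 SD
   on PC1/PC2 of the gene or IR matrix).
2. **Differential expression**: per-feature moderated t with empirical-Bayes
   variance shrinkage (method-of-moments prior, optional intensity trend),
   Benjamini–Hochberg FDR, and isoform-specific DE = transcripts significant
   at FDR 5% whose parent gene is not.
3. **Network inference** (per group): pairwise mutual information
   (Gaussian-copula estimator, MI = −½ln(1−ρ²) in nats, or binned with
   Miller–Madow correction), data-processing-inequality pruning of every
   triangle's dominated edge (simultaneous, order-independent; exact per an
   exhaustive oracle), removal of same-gene edges, then per-edge-type
   thresholding at the affected network's median MI.
4. **Differential network analysis**: hubs (degree ≥ 10), common hubs,
   unique/shared/attenuated partition of common-hub edges (an edge is unique
   only if absent from the *unthresholded* other network), master hubs
   (degree ≥ 10 and ≥ 2-fold the node's degree in the unthresholded other
   network), hop neighborhoods, TE-TE vs IR-IR subnetwork overlap on the
   gene-pair level, and hub modality composition.
5. **Validation**: 100 degree-biased edge-resampling surrogates per network,
   hashed Weisfeiler–Lehman subtree embeddings (3 iterations, 128 dims),
   PCA to 10 components, and repeated stratified 80/20 logistic regression;
   the mean test accuracy measures whether the two networks differ beyond
   perturbation noise (identical networks score ~0.5).

A fully parameterized simulator (`sim_config()`, `build_ground_truth()`,
`simulate_counts()`) generates two-group negative-binomial gene counts with
latent co-expression modules, Dirichlet-multinomial transcript splits,
planted master hubs, group-specific isoform-usage switches with unchanged
gene totals, and nuisance covariates — so the whole pipeline is testable
without any external data. See `vignettes/isorewire-methods.Rmd` for the
model, parameter meanings, and design rationale.

## Worked example

```r
library(isorewire)
report <- run_pipeline(pipeline_config(sim = sim_config(seed = 1), seed = 1),
                       outdir = "isorewire_run")
print(report)
```

```
isorewire pipeline summary (seed 1)
  samples used: 188 (37 outliers removed)
  DE: 23 genes, 63 transcripts, 25 isoform-specific
  affected_raw: 824 nodes, 1721 edges (TE-TE 528, TE-IR 429, IR-IR 764)
  unaffected_raw: 824 nodes, 2324 edges (TE-TE 768, TE-IR 802, IR-IR 754)
  affected_thr: 824 nodes, 861 edges (TE-TE 264, TE-IR 215, IR-IR 382)
  unaffected_thr: 824 nodes, 1373 edges (TE-TE 226, TE-IR 764, IR-IR 383)
  hubs: 11 affected, 13 unaffected, 8 common
  master hubs: affected 6, unaffected 5
  validation accuracy: 1
```

Reading this: of 225 simulated samples, 37 were flagged as PCA outliers; 23
genes and 63 transcripts are differentially expressed at FDR 5%, 25 of those
transcripts without gene-level DE. The affected network keeps 861 of 1,721
edges after median thresholding (~half per edge type, by construction). The
validation accuracy of 1.0 says the perturbed surrogates of the two networks
are perfectly separable — the planted rewiring dominates perturbation noise.

The master-hub table recovers the five hubs the simulator planted at a
2.5-fold connectivity increase:

```r
head(report$details$diffnet$master_a[, c("node_id", "modality",
     "degree_focal", "degree_other_unthresh", "fold")])
```

```
  node_id modality degree_focal degree_other_unthresh     fold
    g0103       TE           33                    12 2.750000
    g0001       TE           32                    14 2.285714
    g0035       TE           32                    13 2.461538
    g0205       TE           30                    12 2.500000
    g0273       TE           23                     9 2.555556
 g0136-t2       IR           10                     3 3.333333
```

```r
sort(report$truth$planted_master_hubs$gene_id)
#> "g0001" "g0035" "g0103" "g0205" "g0273"
```

All artifacts (corrected matrices, DE tables, edge lists, GraphML networks,
hub/master-hub tables, thresholds, validation accuracy) are written under
`outdir`, each stamped with the configuration digest and seed. Real count
matrices are supplied via `pipeline_config(paths = list(...))` with TSV (or
MatrixMarket) counts, a sample table, and a transcript-to-gene map.

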