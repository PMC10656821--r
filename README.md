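# hncmeta

Cross-cohort meta-analysis of prognostic gene expression in head and
neck cancer (HNC).

Individual HNC expression studies are small and noisy, span two decades
of platforms, and annotate different clinical outcomes. `hncmeta`
implements a harmonize-then-combine screening strategy: each cohort is
preprocessed to a common representation, every gene is tested for
association with three outcomes *within* each study, and the per-study
statistics are pooled *across* studies into a single meta-z score per
gene and outcome. Downstream, prognostic genes are clustered by
co-expression and characterized by gene-set enrichment. The package is
aimed at analysts who have (or can simulate) a compendium of
genes-by-samples expression matrices with per-sample clinical tables.

## The statistics at the core

Per study, for each gene with standardized expression
*x* (mean 0, SD 1 within study):

* **Survival** — univariate Cox proportional hazards; the statistic is
  the Wald z = beta / SE(beta) (Efron ties), so z > 0 means higher
  expression, higher hazard.
* **Lymph-node metastasis (LNM)** — Cohen's d between LNM+ and LNM0
  tumors, d = (m1 − m0)/s_pooled, with large-sample variance
  v = (n1+n0)/(n1·n0) + d²/(2(n1+n0)).
* **Tumor grade (1–4, ordinal)** — simple linear regression of
  expression on grade; the statistic is the slope t.

Across studies:

* Survival and grade z-scores combine by **Liptak's weighted
  (Stouffer) meta-z** with square-root-of-sample-size weights,
  Z = Σ √n_i · z_i / √(Σ n_i).
* LNM effect sizes pool under **DerSimonian–Laird random effects**:
  τ² = max(0, (Q − (k−1)) / (Σw − Σw²/Σw)) with w = 1/v, then
  pooled d = Σ w*·d / Σ w*, SE = 1/√(Σ w*), meta-z = pooled/SE with
  w* = 1/(v + τ²).

Genes are called prognostic at |meta-z| ≥ 3.09 (the 0.001 standard
normal quantile, inclusive), subject to eligibility: measured in ≥ 2
studies (survival, grade) or in at least half of the studies (LNM).
Prognostic genes are then clustered by co-expression with a
Phenograph-style procedure (kNN graph on gene profiles,
shared-neighbor Jaccard weights, Louvain communities), and rankings of
meta-z feed preranked GSEA (weighted Kolmogorov–Smirnov running sum,
gene-label permutation null) and hypergeometric overrepresentation
with Benjamini–Hochberg adjustment.

Because the real compendium is large and partly access-controlled, the
package ships a seeded synthetic-compendium generator
(`simulate_compendium()`) that emulates its structure — heterogeneous
study sizes, platform-specific gene coverage, probe-level redundancy,
censored survival, binary LNM, ordinal grade, HPV status, correlated
gene modules — with planted per-gene effects recorded in a ground-truth
table, so every stage is testable.

## Worked example

```r
library(hncmeta)

cfg <- sim_config(
  n_studies = 6, samples_per_study = c(80, 120), n_genes = 500,
  n_modules = 2, module_size = 40, core_fraction = 0.5,
  effects = list(lnm = setNames(c(rep(-0.8, 40), rep(0.8, 40)),
                                sprintf("G%05d", 1:80))),
  seed = 101)
comp <- simulate_compendium(cfg)
studies <- lapply(comp$cohorts, harmonize_study)
fit <- hnc_meta(studies, outcome = "lnm")
summary(fit)
#> Meta-analysis of gene association with lnm
#>   studies: 6 (n = 611); genes combined: 502 (0 ineligible)
#>   prognostic at |meta-z| >= 3.09: 40 pro, 41 anti
#>   strongest associations:
#>  gene_id    meta_z n_studies label
#>   G00034 -12.25230         6  anti
#>   G00011 -11.42392         6  anti
#>   G00037 -11.34895         6  anti
#>   G00020 -11.30468         6  anti
#>   G00040 -11.28961         6  anti

labels <- setNames(fit$results$label, fit$results$gene_id)
cl <- cluster_prognostic_genes(studies, prognostic_genes(fit),
                               labels = labels, k = 15, seed = 1)
cl
#> Co-expression clustering: 80 genes in 2 clusters (modularity 0.494)
#>   1 genes dropped by the complete-data rule (retention 99%)
#>   sizes: 40 (anti), 40 (pro)
```

Reading the output: 40 genes were planted with d = −0.8 (higher
expression in node-negative tumors) and 40 with d = +0.8; the
meta-analysis recovers all 80 with the correct direction (one
borderline null gene crosses the threshold), and the clustering
recovers the two planted co-expression modules, each annotated with
the majority direction of its members. `fit` is an ordinary model
object: `coef()` returns the named meta-z vector, `as.data.frame()`
the full per-gene table, and `plot()` a meta-z histogram with the
±3.09 thresholds.

The whole chain — simulate, harmonize, per-study statistics,
meta-combination, clustering, signature scores with HPV adjustment,
enrichment, recovery report — runs as one call:

```r
res <- run_pipeline(pipeline_config(seed = 1, outdir = "run1"))
```

which writes one TSV per stage plus a log echoing every policy
constant, and is byte-reproducible for a fixed config and seed.

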