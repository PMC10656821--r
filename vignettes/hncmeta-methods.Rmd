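---
title: "Methods: cross-cohort meta-analysis of prognostic genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-cohort meta-analysis of prognostic genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hncmeta)
```

## The problem and the overall model

Head and neck cancer (HNC) expression cohorts are individually too
small to screen ~20,000 genes for prognostic association: a single
study of 50–500 tumors has little power at the stringent thresholds
genome-wide screening demands, and platform differences make naive
pooling of expression values meaningless. `hncmeta` therefore treats
each study as its own experiment and pools *statistics*, not data.

Within study $s$, expression of each gene is reduced to a standard
score $x$ (mean 0, SD 1 across that study's samples). Three per-study
statistics are defined:

* survival: the Wald $z = \hat\beta/\mathrm{SE}(\hat\beta)$ from a
  univariate Cox proportional-hazards fit of the outcome on $x$,
  positive when higher expression predicts higher hazard;
* lymph-node metastasis (LNM): Cohen's
  $d = (\bar x_1 - \bar x_0)/s_\mathrm{pooled}$ between LNM+ and LNM0
  tumors with large-sample variance
  $v = \frac{n_1+n_0}{n_1 n_0} + \frac{d^2}{2(n_1+n_0)}$;
* grade: the slope $t$-statistic from a simple linear regression of
  expression on grade coded 1–4. (For simple regression the
  $t$-statistic is identical whichever variable is treated as the
  response, so the choice of direction is inconsequential.)

Across studies, survival and grade $z$-scores combine by Liptak's
weighted (Stouffer) method with $\sqrt{n_s}$ weights,
$Z = \sum_s \sqrt{n_s}\, z_s \big/ \sqrt{\sum_s n_s}$, which is exact
standard normal under the null when the inputs are. LNM effect sizes
pool under DerSimonian–Laird (DL) random effects: the moment estimator
$\hat\tau^2 = \max\!\big(0,\, (Q-(k-1))/(\sum w - \sum w^2/\sum w)\big)$
with fixed-effect weights $w = 1/v$, then inverse-variance weights
$w^* = 1/(v+\hat\tau^2)$ give the pooled $d$, its standard error and
the meta-z. A gene is called prognostic when $|Z| \ge 3.09$, the upper
standard normal quantile at $p = 0.001$ rounded to two decimals,
applied inclusively.

Key modeling assumptions, stated plainly: proportional hazards within
each study; approximate normality of the per-study statistics (good at
the study floors enforced below); independence of studies; and, for
the Liptak combination, absence of systematic between-study
heterogeneity (the LNM analysis, which uses an effect-size metric,
gets an explicit $\tau^2$ instead).

## Eligibility floors and the threshold policy

All numeric policy constants live in one object,
`threshold_policy()`:

| constant | default | role |
|---|---|---|
| `z_threshold` | 3.09 | inclusive meta-z cutoff, $p<0.001$ per tail |
| `min_studies_survival` / `min_studies_grade` | 2 | a gene must be measured in at least two studies to be combined |
| `min_study_fraction_lnm` | 0.5 | LNM genes must be measured in at least half of the eligible studies |
| `survival_floor` | 20 | minimum samples with survival data (and ≥ 2 events) per study |
| `lnm_group_floor` | 5 | minimum samples per LNM group per study |
| `adjusted_floor` | 10 | minimum complete cases for covariate-adjusted signature models |
| `clustering_coverage` | 0.80 | per-sample gene-coverage rule for the clustering matrix |

The floors keep the per-study statistics in the regime where their
normal approximations hold; the half-of-studies rule for LNM prevents
a gene measured in one small platform from being "pooled".

## Per-study preprocessing

`harmonize_study()` applies, in a fixed order: (1) missingness
filtering, samples before genes, each at an inclusive 10% threshold;
(2) quantile normalization; (3) maxmean probe collapse (per gene, keep
the probe with the largest mean across samples); (4) log2 transform
with offset 1 when the input is linear-scale (the scale is declared
per study, never guessed — a `guess_log_scale()` heuristic exists but
is not used implicitly); (5) per-gene standardization with the sample
(n−1) SD. A sex-concordance QC compares the sign of XIST − RPS4Y1
(log2) against annotated sex and reports the discordance fraction;
it flags mislabeled clinical tables without failing the run.

Numerical choices worth knowing:

* Quantile normalization maps each column onto the vector of row-wise
  means of sorted columns; tied entries within a column receive the
  *mean of the reference values over their rank span*. This exact tie
  rule is implemented in the package (it differs from interpolation-at
  -average-rank dialects for tie spans longer than two) and makes the
  operation idempotent to 1e-10.
* Maxmean ties are broken by the lexicographically smallest probe id,
  so the collapse is deterministic across platforms and sessions.
* Zero-variance genes cannot be standardized; they are dropped with a
  warning rather than propagating NaN.
* Missing entries are excluded pairwise from means and SDs and stay
  missing; quantile normalization is applied to complete submatrices
  only.

For clustering, `assemble_complete_matrix()` restricts each study to
samples observed for ≥ 80% of the gene list (a study that measures
less than 80% of the list loses all its samples), concatenates the
survivors, and keeps genes complete across all retained columns. The
retained/input gene ratio is reported as an integer percentage
(half-up rounding, the convention used for every printed percentage
in the package).

## The synthetic compendium

`sim_config()`/`simulate_compendium()` generate the study conditions
the method is designed for: by default 20 studies of 20–500 tumors,
each study measuring a platform-specific random subset of genes (60 to
100%), with a configurable "core" fraction (default 0.5) measured by
every study so the clustering matrix cannot degenerate. Expression is
lognormal: a per-gene Gaussian baseline (mean 7, SD 1 on log2 scale)
plus a latent unit-variance component, exponentiated to a nonnegative
linear scale and expanded to 1–3 probes per gene (constant per-probe
offsets plus optional noise), so the log2/quantile/maxmean machinery
downstream is exercised meaningfully.

Module structure: the first `n_modules * module_size` genes form
consecutive blocks; within a block the latent value is
$\lambda f + \sqrt{1-\lambda^2}\,\varepsilon$ with a shared per-sample
factor $f$, so the within-module correlation is
$\lambda^2/(\lambda^2 + (1-\lambda^2)\sigma^2_\varepsilon)$. The
default loading 0.8 is an artifact choice — the real compendium's
correlation structure is unknown — and is flagged as such.

Outcomes are generated outcome-first: LNM status and grade are drawn
from their marginals (default prevalence 0.5; grade probabilities
0.10/0.45/0.35/0.10, the typical predominance of moderately
differentiated tumors), and the planted shift ($d$ per LNM+ sample,
slope per grade level) is then *added* to the effect genes. This makes
the true standardized mean difference exactly the configured $d$ — the
estimand matches the generative parameter by construction, which is
what makes the recovery tests sharp. Survival times are exponential
with hazard $h_0 \exp(\sum_g \beta_g x_g)$ over the survival-effect
genes (default baseline 0.02/month, i.e. median ~35 months at the
null), censored by an independent uniform time tuned numerically to
the target censoring fraction (default 0.5) — the simplest model in
which the Cox partial-likelihood z is well calibrated. HPV status can
optionally confound: a log-odds shift on LNM plus a mean shift on the
first module's genes, which is what the covariate-adjusted signature
models are meant to remove.

What the generator does **not** emulate: batch effects needing
empirical-Bayes correction, tumor purity variation, platform-specific
intensity distributions, non-exponential hazards, informative
censoring, or missing clinical annotations beyond whole outcomes.
Passing recovery tests therefore demonstrate that the statistical
machinery is correct and calibrated under the stated generative model,
not that real-data preprocessing artifacts are handled.

## Clustering, enrichment, signatures

Prognostic genes are clustered Phenograph-style: Euclidean kNN on
standardized gene profiles (equivalent in rank to correlation distance
for standardized rows), default $k = 30$ (the common Phenograph
default; the appropriate $k$ for a given compendium is a judgment
call and is exposed as a parameter), shared-neighbor Jaccard edge
weights with zero-weight edges dropped, and Louvain modularity
communities. Determinism is by construction: kNN ties break on gene
id, the gene list is sorted before graph construction (input-order
invariance), and the Louvain seed is fixed. Small clusters are kept
as-is; no minimum-size merging. Each cluster is annotated with the
majority pro/anti label of its members.

Preranked GSEA uses the weighted Kolmogorov–Smirnov running sum
(exponent 1 by default; exponent 0 recovers the classic unweighted
statistic, invariant under monotone transforms of the ranking) with a
*gene-label* permutation null — the only valid permutation scheme for
preranked input — at 10,000 permutations by default. NES normalizes
the ES by the mean |null ES| of matching sign; p-values carry a +1
pseudocount, so the smallest attainable p is 1/(n_perm+1): deep tails
are bounded, not estimated, which is acceptable because no conclusion
here depends on tail magnitudes. Ranking ties break on gene id. The
set-size filter (15–500) is applied *after* intersecting each set with
the ranked universe, matching the behavior of the fgsea family and
keeping the filter meaningful per analysis. Overrepresentation is an
upper-tail hypergeometric test with the meta-analysis universe as
background and Benjamini–Hochberg adjustment.

Signature scores are per-sample means of standardized expression over
the signature genes present (a warning fires below 80% coverage).
Covariate-adjusted association uses Cox (survival) or logistic (LNM)
regression of outcome on score plus covariates, studies entering only
with ≥ 10 complete cases; logistic separation is flagged. Group
contrasts use the two-sided Wilcoxon rank-sum test, exact when both
groups have ≤ 25 observations and no ties (an explicit testability
choice), with continuity-corrected normal approximation otherwise.

## Design decisions that were genuinely open

* **LNM sign convention.** The package fixes: positive meta-z ⇔
  higher expression in LNM+ ⇔ "pro-LNM". For survival, "anti" marks
  adverse genes (positive z) and "pro" favorable ones, following the
  field's pro-/anti-survival naming.
* **Random-effects estimator.** DerSimonian–Laird with standard
  inverse-variance weights is the default; sample size enters through
  $v$. A pure $\sqrt{n}$-weighted Liptak combination of the per-study
  SMD z-scores is available (`lnm_weighting = "sqrt_n"`) for
  sensitivity analysis.
* **No small-sample corrections by default.** Cohen's d is used
  without the Hedges correction (available as `hedges = TRUE`); no
  Knapp–Hartung adjustment; no multiple-testing correction on meta-z —
  the fixed 3.09 cutoff is the decision rule.
* **Cox ties** use the Efron approximation, the robust default of
  standard survival software.
* **Louvain, not Leiden**, for fidelity to the reference clustering
  procedure; the graph construction is deliberately modular so a
  different community detector can be substituted.

## Degenerate inputs and failure behavior

Zero-variance genes: skipped with a warning (standardization) or an
error (single-gene statistics). Monotone likelihood in a Cox fit
(|beta| > 15 or non-finite): the gene is skipped in that study with a
message. Studies below an eligibility floor are excluded from that
outcome only, and the exclusion is logged. An edgeless gene graph
degenerates to singleton clusters with a warning. Empty matrices after
filtering raise errors that name the counts involved.

## Problem sizes used by the test suite

The packaged experiments run at desk scale, chosen so each property is
measured with adequate Monte-Carlo precision: null calibration uses 20
studies of 100 samples and 5,000 null genes (binomial SE ≈ 0.0006 at
the nominal 0.002 rejection rate); effect recovery uses |d| = 0.8 in
10 studies of 100 (expected meta-z ≈ 12, far beyond 3.09, so
sensitivity ≥ 0.99 is an analytic consequence, and the measured value
confirms the implementation); Cox coefficient recovery uses 200
replicates at n = 500; module recovery uses 3 modules of 50 genes at
loading 0.8 across 10 Louvain seeds. The headline gene counts of a
real 29-cohort compendium are functions of that specific data
resource and are not reproduced by simulation.

## Known limitations

Per-gene models are univariate (the only covariate adjustment is at
the signature level); the DL estimator is known to underestimate
$\tau^2$ for very few studies; empirical permutation p-values cannot
resolve tails below 1/(n_perm+1); and the generator's module/effect
independence (effect genes disjoint from unrelated modules by default)
is cleaner than real transcriptional covariance, where prognostic
genes are embedded in broader programs.
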