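Package: hncmeta
Title: Multi-Cohort Meta-Analysis of Prognostic Genes in Head and Neck Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonizes many bulk gene-expression cohorts of head and neck
    cancer and screens every gene for association with patient survival
    (per-study Cox regression), lymph-node metastasis (standardized mean
    differences pooled by DerSimonian-Laird random effects), and tumor
    grade (ordinal linear regression), combining per-study statistics into
    cross-study meta-z scores by Liptak's weighted (Stouffer) method.
    Prognostic genes are classified at |meta-z| >= 3.09, clustered by
    co-expression with a Phenograph-style kNN/Jaccard/Louvain procedure,
    scored as signatures with optional HPV adjustment, and tested for
    gene-set enrichment (preranked GSEA) and overrepresentation
    (hypergeometric). Includes a seeded synthetic-compendium generator with
    planted effects so the whole pipeline is testable against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    survival,
    igraph,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    fgsea,
    limma,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
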