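# Shared fixtures, built once per test run. Sizes are kept small; the
# heavier simulation experiments live in test-acceptance.R.

# A compendium with planted LNM, survival and grade effects and two
# co-expression modules carrying the LNM effects.
fixture_config <- function(seed = 42) {
  sim_config(
    n_studies = 4L, samples_per_study = c(60L, 80L), n_genes = 300L,
    n_modules = 2L, module_size = 20L, module_loading = 0.8,
    core_fraction = 0.5, gene_coverage = c(0.7, 1.0),
    probes_per_gene = c(1L, 3L), probe_noise_sd = 0.1,
    effects = list(
      lnm = stats::setNames(c(rep(-0.8, 20), rep(0.8, 20)),
                            sprintf("G%05d", 1:40)),
      survival = stats::setNames(rep(0.6, 10), sprintf("G%05d", 61:70)),
      grade = stats::setNames(rep(0.4, 10), sprintf("G%05d", 81:90))),
    seed = seed)
}

fixture_compendium <- function() {
  if (is.null(.fixture_env$comp))
    .fixture_env$comp <- simulate_compendium(fixture_config())
  .fixture_env$comp
}

fixture_studies <- function() {
  if (is.null(.fixture_env$studies))
    .fixture_env$studies <- lapply(fixture_compendium()$cohorts,
                                   harmonize_study)
  .fixture_env$studies
}

.fixture_env <- new.env(parent = emptyenv())

# tiny matrix helper
mk_matrix <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("g%d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a
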