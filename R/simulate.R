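#' Configuration for the synthetic multi-study compendium
#'
#' Describes a simulated head-and-neck-cancer expression compendium:
#' a set of studies with heterogeneous sample sizes and platform-specific
#' gene coverage, block-correlated gene modules, censored survival times,
#' binary lymph-node-metastasis (LNM) status, ordinal tumor grade (1-4),
#' HPV status as a potential confounder, and planted per-gene effects.
#' Defaults emulate the structure of the real compendium the method was
#' designed for: 20 studies of 20-500 primary tumors each, lognormal
#' linear-scale expression, roughly half of patients experiencing an event.
#'
#' @param n_studies number of cohorts.
#' @param samples_per_study integer range \code{c(min, max)}; each study's
#'   size is drawn uniformly from it.
#' @param n_genes number of genes (module genes are the first
#'   \code{n_modules * module_size} of them, in consecutive blocks).
#' @param probes_per_gene integer range; per study, each gene emits this
#'   many probes.
#' @param probe_noise_sd SD of probe-level noise on the log2 scale.
#' @param gene_coverage range in (0, 1]: the fraction of genes a study's
#'   platform measures, drawn uniformly per study.
#' @param core_fraction fraction of genes measured by every study
#'   (guarantees clusterable complete data); must cover the module genes.
#' @param n_modules,module_size,module_loading correlated gene blocks:
#'   within a module, a gene's latent value is
#'   \code{loading * factor + sqrt(1 - loading^2) * noise}, so the
#'   within-module correlation is \code{loading^2 / (loading^2 +
#'   (1 - loading^2) * noise_sd^2)}.
#' @param effects named list with optional elements \code{survival}
#'   (named vector of log-hazard per SD), \code{lnm} (named vector of
#'   standardized mean differences d), \code{grade} (named vector of
#'   per-grade-level slopes); names are gene ids.
#' @param lnm_prevalence probability of LNM+.
#' @param grade_probs length-4 probability vector for grades 1-4.
#' @param hpv_prevalence probability of HPV+.
#' @param hpv_confounding \code{NULL}, or a list with \code{lnm_log_odds}
#'   (log-odds shift of LNM for HPV+ patients) and \code{module_shift}
#'   (mean shift added to module-1 genes of HPV+ patients).
#' @param censoring_rate target fraction of censored survival times.
#' @param baseline_hazard exponential baseline hazard per month.
#' @param noise_sd SD of per-gene idiosyncratic noise on the latent scale.
#' @param sex_markers if \code{TRUE}, append XIST and RPS4Y1 rows whose
#'   expression tracks annotated sex, enabling the sex-concordance QC.
#' @param seed integer seed; the whole compendium is a deterministic
#'   function of the configuration including the seed.
#' @return an object of class \code{sim_config}.
#' @seealso [simulate_compendium()]
#' @export
sim_config <- function(n_studies = 20L,
                       samples_per_study = c(20L, 500L),
                       n_genes = 2000L,
                       probes_per_gene = c(1L, 3L),
                       probe_noise_sd = 0.1,
                       gene_coverage = c(0.6, 1.0),
                       core_fraction = 0.5,
                       n_modules = 3L,
                       module_size = 50L,
                       module_loading = 0.8,
                       effects = list(),
                       lnm_prevalence = 0.5,
                       grade_probs = c(0.10, 0.45, 0.35, 0.10),
                       hpv_prevalence = 0.25,
                       hpv_confounding = NULL,
                       censoring_rate = 0.5,
                       baseline_hazard = 0.02,
                       noise_sd = 1,
                       sex_markers = TRUE,
                       seed = 1L) {
  stopifnot(n_studies >= 1, length(samples_per_study) == 2,
            samples_per_study[1] >= 2,
            samples_per_study[1] <= samples_per_study[2],
            n_genes >= 1, length(probes_per_gene) == 2,
            probes_per_gene[1] >= 1,
            probes_per_gene[1] <= probes_per_gene[2],
            probe_noise_sd >= 0,
            length(gene_coverage) == 2,
            gene_coverage[1] > 0, gene_coverage[2] <= 1,
            gene_coverage[1] <= gene_coverage[2],
            core_fraction > 0, core_fraction <= 1,
            n_modules >= 0, module_size >= 0,
            module_loading >= 0, module_loading < 1,
            lnm_prevalence >= 0, lnm_prevalence <= 1,
            length(grade_probs) == 4, all(grade_probs >= 0),
            hpv_prevalence >= 0, hpv_prevalence <= 1,
            censoring_rate >= 0, censoring_rate < 1,
            baseline_hazard > 0, noise_sd > 0)
  if (abs(sum(grade_probs) - 1) > 1e-9)
    stop("grade_probs must sum to 1")
  if (n_modules * module_size > n_genes)
    stop("module_size * n_modules exceeds n_genes")
  if (n_modules * module_size > ceiling(core_fraction * n_genes))
    stop("core_fraction too small to cover all module genes")
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  for (kind in names(effects)) {
    if (!kind %in% c("survival", "lnm", "grade"))
      stop("unknown effect kind: ", kind)
    bad <- setdiff(names(effects[[kind]]), gene_ids)
    if (length(bad))
      stop("effect spec references unknown genes: ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!is.null(hpv_confounding)) {
    stopifnot(is.list(hpv_confounding),
              all(c("lnm_log_odds", "module_shift") %in%
                    names(hpv_confounding)))
    if (n_modules < 1)
      stop("hpv_confounding requires at least one module")
  }
  structure(list(n_studies = as.integer(n_studies),
                 samples_per_study = as.integer(samples_per_study),
                 n_genes = as.integer(n_genes),
                 probes_per_gene = as.integer(probes_per_gene),
                 probe_noise_sd = probe_noise_sd,
                 gene_coverage = gene_coverage,
                 core_fraction = core_fraction,
                 n_modules = as.integer(n_modules),
                 module_size = as.integer(module_size),
                 module_loading = module_loading,
                 effects = effects,
                 lnm_prevalence = lnm_prevalence,
                 grade_probs = grade_probs,
                 hpv_prevalence = hpv_prevalence,
                 hpv_confounding = hpv_confounding,
                 censoring_rate = censoring_rate,
                 baseline_hazard = baseline_hazard,
                 noise_sd = noise_sd,
                 sex_markers = isTRUE(sex_markers),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Synthetic compendium config: %d studies, %d genes, seed %d\n",
              x$n_studies, x$n_genes, x$seed))
  cat(sprintf("  samples/study %d-%d; coverage %.2f-%.2f (core %.2f)\n",
              x$samples_per_study[1], x$samples_per_study[2],
              x$gene_coverage[1], x$gene_coverage[2], x$core_fraction))
  cat(sprintf("  %d modules of %d genes, loading %.2f\n",
              x$n_modules, x$module_size, x$module_loading))
  n_eff <- vapply(x$effects, length, 0L)
  if (length(n_eff))
    cat("  planted effects:",
        paste(sprintf("%s=%d", names(n_eff), n_eff), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate censored survival times from an exponential hazard
#'
#' Event times are exponential with rate
#' \code{baseline_hazard * exp(linear_predictor)}; censoring times are
#' uniform on (0, c) with c tuned numerically so the expected event
#' fraction over the supplied linear predictors is
#' \code{1 - censoring_rate}. With \code{censoring_rate = 0} no
#' observation is censored.
#'
#' @param linear_predictor per-sample log relative hazard.
#' @param baseline_hazard exponential rate per month (> 0).
#' @param censoring_rate target censored fraction in [0, 1).
#' @param seed optional integer seed.
#' @return data.frame with columns \code{time_months} (> 0) and
#'   \code{event} (1 = event observed, 0 = censored).
#' @examples
#' s <- simulate_survival(rep(0, 5), 0.1, 0, seed = 1)
#' all(s$event == 1)
#' @export
simulate_survival <- function(linear_predictor, baseline_hazard,
                              censoring_rate, seed = NULL) {
  stopifnot(baseline_hazard > 0, is.numeric(linear_predictor))
  if (censoring_rate >= 1) stop("censoring_rate must be < 1")
  if (censoring_rate < 0) stop("censoring_rate must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  rates <- baseline_hazard * exp(linear_predictor)
  t_event <- stats::rexp(length(rates), rate = rates)
  if (censoring_rate == 0) {
    return(data.frame(time_months = t_event,
                      event = rep(1L, length(rates))))
  }
  # expected event fraction if C ~ U(0, c):
  # P(T <= C) = 1 - (1 - exp(-r c)) / (r c), averaged over samples
  event_frac <- function(cc) {
    mean(1 - (1 - exp(-rates * cc)) / (rates * cc))
  }
  target <- 1 - censoring_rate
  lo <- 1e-8 / baseline_hazard
  hi <- 1e8 / baseline_hazard
  cc <- stats::uniroot(function(x) event_frac(x) - target,
                       lower = lo, upper = hi, tol = 1e-10)$root
  t_cens <- stats::runif(length(rates), 0, cc)
  data.frame(time_months = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens))
}

#' Expand a gene-level matrix to probe level
#'
#' Emulates microarray probe redundancy: each gene emits between
#' \code{probes_per_gene[1]} and \code{probes_per_gene[2]} probes, each
#' equal to the gene value plus a constant per-probe offset plus
#' independent noise. The first probe of every gene has offset 0, so a
#' single-probe, zero-noise expansion reproduces the gene matrix exactly
#' (up to row renaming). Offsets of additional probes are drawn uniformly
#' from (-1, 0), so the first probe has the maximum mean and maxmean
#' collapse recovers the original row when noise is absent.
#'
#' @param gene_matrix genes x samples numeric matrix (any scale on which
#'   additive probe offsets make sense, e.g. log2).
#' @param probes_per_gene integer range \code{c(min, max)}.
#' @param probe_noise_sd SD of independent per-entry probe noise (>= 0).
#' @param seed optional integer seed.
#' @return list with \code{probe_matrix} (probes x samples) and
#'   \code{probe_gene_map} (named character vector, probe id -> gene id).
#' @export
expand_to_probes <- function(gene_matrix, probes_per_gene = c(1L, 3L),
                             probe_noise_sd = 0, seed = NULL) {
  check_matrix(gene_matrix, "gene_matrix")
  stopifnot(probe_noise_sd >= 0, length(probes_per_gene) == 2,
            probes_per_gene[1] >= 1,
            probes_per_gene[1] <= probes_per_gene[2])
  if (!is.null(seed)) set.seed(seed)
  genes <- rownames(gene_matrix)
  if (probes_per_gene[2] == 1L && probe_noise_sd == 0) {
    probe_matrix <- gene_matrix
    rownames(probe_matrix) <- sprintf("%s_p1", genes)
    return(list(probe_matrix = probe_matrix,
                probe_gene_map = stats::setNames(genes,
                                                 rownames(probe_matrix))))
  }
  k <- if (probes_per_gene[1] == probes_per_gene[2]) {
    rep(probes_per_gene[1], length(genes))
  } else {
    sample(probes_per_gene[1]:probes_per_gene[2], length(genes),
           replace = TRUE)
  }
  rows <- vector("list", length(genes))
  maps <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    offsets <- c(0, stats::runif(k[i] - 1L, -1, 0))
    block <- matrix(rep(gene_matrix[i, ], each = k[i]),
                    nrow = k[i], ncol = ncol(gene_matrix)) + offsets
    if (probe_noise_sd > 0)
      block <- block + matrix(stats::rnorm(length(block), 0, probe_noise_sd),
                              nrow = k[i])
    rownames(block) <- sprintf("%s_p%d", genes[i], seq_len(k[i]))
    rows[[i]] <- block
    maps[[i]] <- stats::setNames(rep(genes[i], k[i]), rownames(block))
  }
  probe_matrix <- do.call(rbind, rows)
  colnames(probe_matrix) <- colnames(gene_matrix)
  list(probe_matrix = probe_matrix,
       probe_gene_map = do.call(c, maps))
}

#' Simulate a multi-study expression compendium with known ground truth
#'
#' Generates \code{config$n_studies} cohorts. Per sample, a latent
#' genes-vector combines module factors (block correlation), idiosyncratic
#' noise, and planted outcome shifts; linear-scale nonnegative expression
#' is \code{2^(baseline + latent)} (lognormal), then expanded to probe
#' level. Clinical outcomes: LNM and grade are drawn first and shift the
#' corresponding effect genes (so the planted standardized mean difference
#' and per-grade slope are exactly the configured values); survival times
#' follow an exponential hazard \code{baseline_hazard * exp(sum(beta *
#' latent))} over the survival-effect genes, with uniform censoring tuned
#' to \code{censoring_rate}. HPV status optionally confounds LNM (log-odds
#' shift) and shifts module-1 genes.
#'
#' @param config a [sim_config()].
#' @return object of class \code{synthetic_compendium}: a list with
#'   \code{cohorts} (each a list with \code{probe_matrix},
#'   \code{probe_gene_map}, \code{clinical}, \code{study_id}),
#'   \code{truth} (per-gene data.frame: \code{gene_id},
#'   \code{true_survival_effect}, \code{true_lnm_effect},
#'   \code{true_grade_slope}, \code{module_id}, \code{is_null}), and the
#'   \code{config}.
#' @examples
#' cfg <- sim_config(n_studies = 2, samples_per_study = c(30, 30),
#'                   n_genes = 50, n_modules = 1, module_size = 10,
#'                   core_fraction = 0.5, seed = 7)
#' comp <- simulate_compendium(cfg)
#' length(comp$cohorts)
#' @export
simulate_compendium <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gene_ids <- sprintf("G%05d", seq_len(config$n_genes))
  n_mod_genes <- config$n_modules * config$module_size
  module_id <- rep(NA_integer_, config$n_genes)
  if (n_mod_genes > 0)
    module_id[seq_len(n_mod_genes)] <-
      rep(seq_len(config$n_modules), each = config$module_size)

  eff <- function(kind) {
    v <- stats::setNames(rep(0, config$n_genes), gene_ids)
    spec <- config$effects[[kind]]
    if (!is.null(spec)) v[names(spec)] <- spec
    v
  }
  beta_surv <- eff("survival")
  d_lnm <- eff("lnm")
  slope_grade <- eff("grade")
  truth <- data.frame(gene_id = gene_ids,
                      true_survival_effect = unname(beta_surv),
                      true_lnm_effect = unname(d_lnm),
                      true_grade_slope = unname(slope_grade),
                      module_id = module_id,
                      is_null = unname(beta_surv == 0 & d_lnm == 0 &
                                         slope_grade == 0),
                      stringsAsFactors = FALSE)

  set.seed(substream_seed(config$seed, "baseline"))
  baseline <- stats::setNames(stats::rnorm(config$n_genes, 7, 1), gene_ids)
  n_core <- ceiling(config$core_fraction * config$n_genes)
  core_genes <- gene_ids[seq_len(n_core)]
  loading <- config$module_loading
  resid_sd <- sqrt(1 - loading^2)

  cohorts <- vector("list", config$n_studies)
  for (s in seq_len(config$n_studies)) {
    set.seed(substream_seed(config$seed, paste0("study", s)))
    study_id <- sprintf("study%02d", s)
    n <- if (config$samples_per_study[1] == config$samples_per_study[2]) {
      config$samples_per_study[1]
    } else {
      sample(config$samples_per_study[1]:config$samples_per_study[2], 1)
    }
    cov_frac <- stats::runif(1, config$gene_coverage[1],
                             config$gene_coverage[2])
    n_meas <- max(n_core, ceiling(cov_frac * config$n_genes))
    extra <- sample(setdiff(gene_ids, core_genes),
                    min(n_meas - n_core, config$n_genes - n_core))
    measured <- gene_ids[gene_ids %in% c(core_genes, extra)]
    sample_ids <- sprintf("%s_s%03d", study_id, seq_len(n))

    # clinical covariates and outcomes (outcome-first generation)
    sex <- ifelse(stats::runif(n) < 0.7, "male", "female")
    age <- round(stats::rnorm(n, 62, 10))
    hpv <- stats::rbinom(n, 1, config$hpv_prevalence)
    lnm_logit <- stats::qlogis(min(max(config$lnm_prevalence, 1e-12),
                                   1 - 1e-12))
    if (!is.null(config$hpv_confounding))
      lnm_logit <- lnm_logit + config$hpv_confounding$lnm_log_odds * hpv
    lnm <- stats::rbinom(n, 1, stats::plogis(lnm_logit))
    grade <- sample.int(4, n, replace = TRUE, prob = config$grade_probs)

    # latent expression: module factor + idiosyncratic noise + shifts
    z <- matrix(stats::rnorm(length(measured) * n, 0, config$noise_sd),
                nrow = length(measured), ncol = n,
                dimnames = list(measured, sample_ids))
    if (config$n_modules > 0) {
      factors <- matrix(stats::rnorm(config$n_modules * n),
                        nrow = config$n_modules)
      in_mod <- !is.na(module_id) & gene_ids %in% measured
      for (g in which(in_mod)) {
        gid <- gene_ids[g]
        z[gid, ] <- loading * factors[module_id[g], ] +
          resid_sd * stats::rnorm(n, 0, config$noise_sd)
      }
    }
    if (!is.null(config$hpv_confounding)) {
      mod1 <- gene_ids[!is.na(module_id) & module_id == 1L]
      mod1 <- intersect(mod1, measured)
      if (length(mod1))
        z[mod1, ] <- z[mod1, ] +
          config$hpv_confounding$module_shift *
            matrix(hpv, nrow = length(mod1), ncol = n, byrow = TRUE)
    }
    dg <- d_lnm[measured]
    if (any(dg != 0))
      z <- z + outer(dg, lnm)
    sg <- slope_grade[measured]
    if (any(sg != 0))
      z <- z + outer(sg, grade - 1)

    bg <- beta_surv[measured]
    lp <- if (any(bg != 0)) drop(crossprod(z[bg != 0, , drop = FALSE],
                                           bg[bg != 0])) else rep(0, n)
    surv <- simulate_survival(lp, config$baseline_hazard,
                              config$censoring_rate)

    log2_expr <- z + baseline[measured]
    if (config$sex_markers) {
      xist <- ifelse(sex == "female", 9, 3) + stats::rnorm(n, 0, 0.5)
      rps4y1 <- ifelse(sex == "male", 9, 3) + stats::rnorm(n, 0, 0.5)
      log2_expr <- rbind(log2_expr,
                         XIST = xist, RPS4Y1 = rps4y1)
    }
    probes <- expand_to_probes(log2_expr, config$probes_per_gene,
                               config$probe_noise_sd)
    cohorts[[s]] <- list(
      probe_matrix = 2^probes$probe_matrix,
      probe_gene_map = probes$probe_gene_map,
      clinical = data.frame(sample_id = sample_ids,
                            time_months = surv$time_months,
                            event = surv$event,
                            lnm_status = lnm,
                            grade = grade,
                            hpv_status = hpv,
                            age = age,
                            sex = sex,
                            stringsAsFactors = FALSE),
      study_id = study_id)
  }
  if (config$sex_markers) {
    truth <- rbind(truth,
                   data.frame(gene_id = c("XIST", "RPS4Y1"),
                              true_survival_effect = 0,
                              true_lnm_effect = 0,
                              true_grade_slope = 0,
                              module_id = NA_integer_,
                              is_null = TRUE,
                              stringsAsFactors = FALSE))
  }
  structure(list(cohorts = cohorts, truth = truth, config = config),
            class = "synthetic_compendium")
}

#' @export
print.synthetic_compendium <- function(x, ...) {
  ns <- vapply(x$cohorts, function(co) ncol(co$probe_matrix), 0L)
  cat(sprintf("Synthetic compendium: %d studies, %d-%d samples (total %d)\n",
              length(x$cohorts), min(ns), max(ns), sum(ns)))
  cat(sprintf("  %d genes in truth table, %d non-null\n",
              nrow(x$truth), sum(!x$truth$is_null)))
  invisible(x)
}

#' Write a synthetic compendium to TSV files
#'
#' Per study: \code{<study>.expr.tsv} (first column \code{probe_id},
#' remaining columns the samples), \code{<study>.clinical.tsv} and
#' \code{<study>.probes.tsv} (probe-to-gene map); plus \code{truth.tsv}
#' and \code{config.R} (the configuration, deparsed losslessly and
#' readable with \code{dget}).
#'
#' @param compendium a [simulate_compendium()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest data.frame (one row per study with the
#'   file paths).
#' @export
write_compendium <- function(compendium, dir) {
  stopifnot(inherits(compendium, "synthetic_compendium"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(compendium$cohorts, function(co) {
    base <- file.path(dir, co$study_id)
    expr <- data.frame(probe_id = rownames(co$probe_matrix),
                       co$probe_matrix, check.names = FALSE,
                       stringsAsFactors = FALSE)
    utils::write.table(expr, paste0(base, ".expr.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(co$clinical, paste0(base, ".clinical.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(probe_id = names(co$probe_gene_map),
                 gene_id = unname(co$probe_gene_map)),
      paste0(base, ".probes.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    data.frame(study_id = co$study_id,
               expr = paste0(base, ".expr.tsv"),
               clinical = paste0(base, ".clinical.tsv"),
               probes = paste0(base, ".probes.tsv"),
               already_log = FALSE,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(compendium$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dput(compendium$config, file.path(dir, "config.R"))
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read one cohort written by [write_compendium()]
#'
#' @param expr_path TSV with first column \code{probe_id}.
#' @param clinical_path TSV clinical table with a \code{sample_id} column.
#' @param probes_path TSV with columns \code{probe_id}, \code{gene_id}.
#' @param study_id study label; defaults to the expression file stem.
#' @return a cohort list as produced by [simulate_compendium()].
#' @export
read_cohort <- function(expr_path, clinical_path, probes_path,
                        study_id = NULL) {
  expr <- utils::read.delim(expr_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  m <- as.matrix(expr[, -1, drop = FALSE])
  rownames(m) <- expr[[1]]
  clinical <- utils::read.delim(clinical_path, stringsAsFactors = FALSE)
  pm <- utils::read.delim(probes_path, stringsAsFactors = FALSE)
  if (!identical(sort(clinical$sample_id), sort(colnames(m))))
    stop("clinical rows and expression columns do not match")
  clinical <- clinical[match(colnames(m), clinical$sample_id), ]
  list(probe_matrix = m,
       probe_gene_map = stats::setNames(pm$gene_id, pm$probe_id),
       clinical = clinical,
       study_id = study_id %||% sub("\\.expr\\.tsv$", "",
                                    basename(expr_path)))
}
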