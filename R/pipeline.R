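#' Default planted-effect specification for the synthetic pipeline
#'
#' Fifty anti-LNM genes (d = -0.8, the first co-expression module),
#' fifty pro-LNM genes (d = +0.8, the second module), twenty-five
#' adverse and twenty-five favorable survival genes (log-hazard +/- 0.5
#' per SD), and twenty-five pro- plus twenty-five anti-grade genes
#' (slope +/- 0.3 per grade level); all remaining genes are null.
#' Survival and grade genes sit outside the modules so module membership
#' does not leak association across outcomes.
#'
#' @param n_genes total genes (must be >= 250).
#' @return named list of effect vectors suitable for
#'   \code{sim_config(effects = ...)}.
#' @export
default_effects <- function(n_genes = 2000L) {
  stopifnot(n_genes >= 250)
  g <- function(i) sprintf("G%05d", i)
  list(
    lnm = stats::setNames(c(rep(-0.8, 50), rep(0.8, 50)), g(1:100)),
    survival = stats::setNames(c(rep(0.5, 25), rep(-0.5, 25)),
                               g(151:200)),
    grade = stats::setNames(c(rep(0.3, 25), rep(-0.3, 25)), g(201:250))
  )
}

#' Pipeline configuration
#'
#' Bundles the simulation block (or a manifest of study files), the
#' threshold policy, and the stage parameters, each with its standard
#' default: meta-z cutoff 3.09, survival minimum 2 studies, LNM
#' half-of-studies rule, LNM group floor 5, survival study floor 20,
#' adjusted-model floor 10, clustering coverage 0.80, kNN k = 30, GSEA
#' set sizes 15-500 with 10000 permutations.
#'
#' @param sim a [sim_config()], or \code{NULL} when \code{manifest}
#'   provides real study files.
#' @param manifest optional data.frame/path listing per-study files (see
#'   [validate_inputs()]).
#' @param policy a [threshold_policy()].
#' @param knn_k kNN neighborhood size for clustering.
#' @param gsea_min_size,gsea_max_size,gsea_permutations GSEA settings.
#' @param seed global integer seed; each stage derives its own
#'   substream from it.
#' @param outdir output directory for stage TSVs and the log.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(sim = sim_config(
                              n_studies = 10L,
                              samples_per_study = c(100L, 100L),
                              n_genes = 2000L,
                              effects = default_effects(2000L),
                              seed = 1L),
                            manifest = NULL,
                            policy = threshold_policy(),
                            knn_k = 30L,
                            gsea_min_size = 15L,
                            gsea_max_size = 500L,
                            gsea_permutations = 10000L,
                            seed = 1L,
                            outdir = tempfile("hncmeta_run_")) {
  if (is.null(sim) && is.null(manifest))
    stop("either a simulation block or a manifest is required")
  if (!is.null(sim)) {
    stopifnot(inherits(sim, "sim_config"))
    sim$seed <- substream_seed(seed, "simulate")
  }
  structure(list(sim = sim, manifest = manifest, policy = policy,
                 knn_k = as.integer(knn_k),
                 gsea_min_size = as.integer(gsea_min_size),
                 gsea_max_size = as.integer(gsea_max_size),
                 gsea_permutations = as.integer(gsea_permutations),
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' Validate a manifest of study files
#'
#' Checks, per study: files exist and parse; probe ids and sample ids
#' are unique; expression columns and clinical rows align; and outcome
#' availability against the study floors (>= 20 samples with survival
#' data and >= 2 events; >= 5 samples per LNM group; >= 2 observed grade
#' levels). Floor violations are warnings (the study is simply excluded
#' from that outcome); structural violations are errors. In strict mode
#' any violation aborts.
#'
#' @param manifest data.frame with columns \code{study_id}, \code{expr},
#'   \code{clinical}, \code{probes}, \code{already_log}, or the path of
#'   a manifest TSV.
#' @param strict abort on any violation?
#' @param policy a [threshold_policy()] supplying the floors.
#' @return data.frame of violations (zero rows when clean) with columns
#'   \code{study_id}, \code{check}, \code{severity}, \code{message}.
#' @export
validate_inputs <- function(manifest, strict = FALSE,
                            policy = threshold_policy()) {
  if (is.character(manifest))
    manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  need <- c("study_id", "expr", "clinical", "probes")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) stop("manifest lacks columns: ",
                         paste(miss, collapse = ", "))
  viol <- list()
  note <- function(study, check, severity, msg) {
    viol[[length(viol) + 1]] <<- data.frame(
      study_id = study, check = check, severity = severity,
      message = msg, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$study_id[i]
    paths <- unlist(manifest[i, c("expr", "clinical", "probes")])
    bad <- !file.exists(paths)
    if (any(bad)) {
      note(sid, "files", "error",
           paste("missing file(s):", paste(paths[bad], collapse = ", ")))
      next
    }
    co <- tryCatch(read_cohort(manifest$expr[i], manifest$clinical[i],
                               manifest$probes[i], sid),
                   error = function(e) e)
    if (inherits(co, "error")) {
      note(sid, "schema", "error", conditionMessage(co))
      next
    }
    if (anyDuplicated(rownames(co$probe_matrix)))
      note(sid, "probe_ids", "error", "duplicated probe ids")
    if (!all(rownames(co$probe_matrix) %in% names(co$probe_gene_map)))
      note(sid, "probe_map", "error", "probe map does not cover matrix")
    cl <- co$clinical
    n_surv <- sum(!is.na(cl$time_months) & !is.na(cl$event))
    if (n_surv < policy$survival_floor ||
        sum(cl$event, na.rm = TRUE) < 2)
      note(sid, "survival_floor", "warning",
           sprintf("%d samples with survival data (< %d) or < 2 events; excluded from survival analysis",
                   n_surv, policy$survival_floor))
    n1 <- sum(cl$lnm_status == 1, na.rm = TRUE)
    n0 <- sum(cl$lnm_status == 0, na.rm = TRUE)
    if (min(n1, n0) < policy$lnm_group_floor)
      note(sid, "lnm_floor", "warning",
           sprintf("%d LNM+ / %d LNM0 (floor %d per group); excluded from LNM analysis",
                   n1, n0, policy$lnm_group_floor))
    if (length(unique(stats::na.omit(cl$grade))) < 2)
      note(sid, "grade_floor", "warning",
           "fewer than 2 observed grade levels; excluded from grade analysis")
  }
  report <- if (length(viol)) do.call(rbind, viol)
            else data.frame(study_id = character(0), check = character(0),
                            severity = character(0),
                            message = character(0))
  if (strict && nrow(report))
    stop("manifest validation failed:\n",
         paste(sprintf("  [%s] %s: %s", report$severity, report$study_id,
                       report$message), collapse = "\n"))
  report
}

#' Classification and clustering recovery against the ground truth
#'
#' Per outcome: sensitivity is the fraction of genes with a planted
#' effect that are labeled prognostic in the correct direction (positive
#' planted effect must yield the positive-association label);
#' the false-positive fraction is the share of genes with no planted
#' effect for that outcome labeled prognostic either way; specificity is
#' its complement. Optionally, the adjusted Rand index between the
#' co-expression clustering and the planted modules (over clustered
#' genes with a known module).
#'
#' @param fits named list of \code{hnc_meta} objects (names among
#'   "survival", "lnm", "grade").
#' @param truth the ground-truth table from [simulate_compendium()].
#' @param clusters optional \code{cluster_assignment}.
#' @return data.frame with one row per outcome (columns
#'   \code{sensitivity}, \code{specificity}, \code{fp_fraction},
#'   \code{n_true}, \code{n_null}) plus an \code{ari} attribute when
#'   clusters are supplied.
#' @export
recovery_report <- function(fits, truth, clusters = NULL) {
  effect_col <- c(survival = "true_survival_effect",
                  lnm = "true_lnm_effect",
                  grade = "true_grade_slope")
  rows <- lapply(names(fits), function(outc) {
    res <- fits[[outc]]$results
    eff <- truth[[effect_col[[outc]]]][match(res$gene_id, truth$gene_id)]
    # positive planted effect corresponds to the adverse/positive label:
    # "anti" for survival (higher hazard), "pro" for LNM and grade
    pos_lab <- if (outc == "survival") "anti" else "pro"
    neg_lab <- if (outc == "survival") "pro" else "anti"
    is_true <- !is.na(eff) & eff != 0
    correct <- (eff > 0 & res$label == pos_lab) |
      (eff < 0 & res$label == neg_lab)
    is_null <- !is.na(eff) & eff == 0
    data.frame(outcome = outc,
               sensitivity = if (any(is_true)) mean(correct[is_true])
                             else NA_real_,
               fp_fraction = if (any(is_null))
                 mean(res$label[is_null] != "ns") else NA_real_,
               specificity = if (any(is_null))
                 mean(res$label[is_null] == "ns") else NA_real_,
               n_true = sum(is_true), n_null = sum(is_null),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(clusters)) {
    memb <- clusters$membership
    mod <- truth$module_id[match(names(memb), truth$gene_id)]
    keep <- !is.na(mod)
    attr(out, "ari") <- if (sum(keep) >= 2)
      mclust::adjustedRandIndex(memb[keep], mod[keep]) else NA_real_
  }
  out
}

write_stage_tsv <- function(df, outdir, name) {
  path <- file.path(outdir, name)
  is_list <- vapply(df, is.list, TRUE)
  for (cn in names(df)[is_list])
    df[[cn]] <- vapply(df[[cn]], paste, "", collapse = ",")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full meta-analysis pipeline
#'
#' simulate (or load) -> harmonize -> per-study statistics -> meta-z
#' combination and classification -> co-expression clustering ->
#' signature scores with HPV adjustment -> enrichment -> recovery
#' report. Every stage writes a TSV into \code{config$outdir}, stage
#' parameters are echoed into \code{pipeline.log}, and the whole run is
#' a deterministic function of the configuration (re-running with the
#' same config and seed reproduces identical result tables).
#'
#' @param config a [pipeline_config()].
#' @return invisibly, an object of class \code{hnc_pipeline}: the fitted
#'   \code{hnc_meta} objects per outcome, cluster assignments,
#'   signature/enrichment tables, the recovery report, and the output
#'   file paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$outdir, "pipeline.log")
  log_lines <- character(0)
  say <- function(stage, msg) {
    line <- sprintf("[%s] %s", stage, msg)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  pol <- config$policy
  say("config", sprintf(
    "seed=%d z_threshold=%.2f min_studies_survival=%d min_study_fraction_lnm=%.2f min_studies_grade=%d survival_floor=%d lnm_group_floor=%d adjusted_floor=%d clustering_coverage=%.2f knn_k=%d gsea_sizes=%d-%d gsea_permutations=%d",
    config$seed, pol$z_threshold, pol$min_studies_survival,
    pol$min_study_fraction_lnm, pol$min_studies_grade,
    pol$survival_floor, pol$lnm_group_floor, pol$adjusted_floor,
    pol$clustering_coverage, config$knn_k, config$gsea_min_size,
    config$gsea_max_size, config$gsea_permutations))

  paths <- list()
  # --- stage: inputs -------------------------------------------------
  if (!is.null(config$sim)) {
    comp <- simulate_compendium(config$sim)
    truth <- comp$truth
    cohorts <- comp$cohorts
    already_log <- rep(FALSE, length(cohorts))
    say("simulate", sprintf("%d studies, %d genes, sim seed %d",
                            length(cohorts), config$sim$n_genes,
                            config$sim$seed))
    paths$truth <- write_stage_tsv(truth, config$outdir, "truth.tsv")
  } else {
    manifest <- config$manifest
    if (is.character(manifest))
      manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE)
    report <- validate_inputs(manifest, strict = FALSE, policy = pol)
    bad <- unique(report$study_id[report$severity == "error"])
    if (length(bad))
      say("validate", paste("dropping studies with errors:",
                            paste(bad, collapse = ", ")))
    manifest <- manifest[!manifest$study_id %in% bad, , drop = FALSE]
    cohorts <- lapply(seq_len(nrow(manifest)), function(i)
      read_cohort(manifest$expr[i], manifest$clinical[i],
                  manifest$probes[i], manifest$study_id[i]))
    already_log <- if ("already_log" %in% names(manifest))
      as.logical(manifest$already_log) else rep(FALSE, nrow(manifest))
    truth <- NULL
    say("load", sprintf("%d studies read from manifest", length(cohorts)))
  }

  # --- stage: harmonize ----------------------------------------------
  studies <- vector("list", length(cohorts))
  for (i in seq_along(cohorts)) {
    studies[[i]] <- harmonize_study(cohorts[[i]],
                                    already_log = already_log[i])
    qc <- studies[[i]]$sex_qc
    say("harmonize", sprintf(
      "%s: %d genes x %d samples; sex discordance %s",
      studies[[i]]$study_id, nrow(studies[[i]]$expression),
      studies[[i]]$n_samples,
      if (is.null(qc) || !is.finite(qc$discordance_fraction)) "NA"
      else sprintf("%.3f", qc$discordance_fraction)))
  }

  # --- stage: meta-analysis per outcome ------------------------------
  fits <- list()
  for (outc in c("survival", "lnm", "grade")) {
    fit <- tryCatch(
      suppressMessages(hnc_meta(studies, outcome = outc, policy = pol)),
      error = function(e) {
        say("meta", sprintf("%s meta-analysis skipped: %s", outc,
                            conditionMessage(e)))
        NULL
      })
    if (is.null(fit)) next
    fits[[outc]] <- fit
    tab <- table(factor(fit$results$label,
                        levels = c("pro", "anti", "ns")))
    say("meta", sprintf("%s: %d studies, %d genes, %d pro / %d anti",
                        outc, length(fit$studies), nrow(fit$results),
                        tab[["pro"]], tab[["anti"]]))
    paths[[paste0("meta_", outc)]] <-
      write_stage_tsv(fit$results, config$outdir,
                      sprintf("meta_%s.tsv", outc))
  }

  # --- stage: co-expression clustering of prognostic genes -----------
  clusters <- list()
  for (outc in intersect(c("survival", "lnm"), names(fits))) {
    res <- fits[[outc]]$results
    prog <- res$gene_id[res$label != "ns"]
    labels <- stats::setNames(res$label, res$gene_id)
    cl <- tryCatch(
      cluster_prognostic_genes(studies, prog, labels = labels,
                               policy = pol, k = config$knn_k,
                               seed = substream_seed(config$seed,
                                                     paste0("cluster_", outc))),
      error = function(e) {
        say("cluster", sprintf("%s clustering skipped: %s", outc,
                               conditionMessage(e)))
        NULL
      })
    if (is.null(cl)) next
    clusters[[outc]] <- cl
    say("cluster", sprintf(
      "%s: %d genes -> %d clusters (modularity %.3f, retention %d%%)",
      outc, length(cl$membership), cl$n_clusters, cl$modularity,
      cl$retention_pct))
    df <- data.frame(gene_id = names(cl$membership),
                     cluster_id = as.integer(cl$membership),
                     cluster_direction =
                       if (is.null(cl$direction)) NA_character_
                       else cl$direction[as.character(cl$membership)],
                     stringsAsFactors = FALSE)
    paths[[paste0("clusters_", outc)]] <-
      write_stage_tsv(df, config$outdir,
                      sprintf("clusters_%s.tsv", outc))
  }

  # --- stage: signature scores with HPV adjustment -------------------
  sig_rows <- list()
  for (outc in intersect(c("survival", "lnm"), names(fits))) {
    res <- fits[[outc]]$results
    for (dir in c("pro", "anti")) {
      sig <- res$gene_id[res$label == dir]
      if (length(sig) < 2) next
      sig_name <- paste(dir, outc, sep = "_")
      per_study <- list()
      for (st in studies) {
        sc <- tryCatch(
          suppressWarnings(signature_score(st$expression, sig, sig_name)),
          error = function(e) NULL)
        if (is.null(sc)) next
        adj <- suppressMessages(tryCatch(
          adjusted_assoc(sc$score, st$clinical,
                         outcome = if (outc == "survival") "survival"
                                   else "lnm",
                         covariates = "hpv_status",
                         floor = pol$adjusted_floor,
                         study_id = st$study_id),
          error = function(e) NULL))
        if (!is.null(adj)) per_study[[st$study_id]] <- adj
      }
      if (!length(per_study)) next
      tab <- do.call(rbind, per_study)
      meta_z <- liptak_meta_z(tab$z, tab$n)
      sig_rows[[sig_name]] <- data.frame(
        signature = sig_name, n_genes = length(sig),
        n_studies = nrow(tab), meta_z_adjusted = meta_z,
        stringsAsFactors = FALSE)
      say("score", sprintf("%s: HPV-adjusted meta-z %.2f over %d studies",
                           sig_name, meta_z, nrow(tab)))
    }
  }
  signatures <- if (length(sig_rows)) do.call(rbind, sig_rows) else NULL
  if (!is.null(signatures))
    paths$signatures <- write_stage_tsv(signatures, config$outdir,
                                        "signature_assoc.tsv")

  # --- stage: enrichment ---------------------------------------------
  gsea <- NULL; overrep <- NULL
  if ("lnm" %in% names(fits)) {
    ranking <- stats::setNames(fits$lnm$results$meta_z,
                               fits$lnm$results$gene_id)
    collection <- reference_collection(names(ranking), truth,
                                       seed = substream_seed(config$seed,
                                                             "genesets"))
    paths$genesets <- file.path(config$outdir, "genesets.gmt")
    write_gmt(collection, paths$genesets)
    filtered <- filter_sets(collection, names(ranking),
                            min_size = config$gsea_min_size,
                            max_size = config$gsea_max_size)
    if (length(filtered)) {
      gsea <- preranked_gsea(ranking, filtered,
                             n_perm = config$gsea_permutations,
                             seed = substream_seed(config$seed, "gsea"))
      say("enrich", sprintf("GSEA on %d sets; top |NES| = %.2f (%s)",
                            nrow(gsea), max(abs(gsea$nes)),
                            gsea$set_name[which.max(abs(gsea$nes))]))
      paths$gsea <- write_stage_tsv(gsea, config$outdir, "gsea_lnm.tsv")
      prog <- fits$lnm$results$gene_id[fits$lnm$results$label == "pro"]
      if (length(prog)) {
        overrep <- overrepresentation(prog, filtered, names(ranking))
        paths$overrep <- write_stage_tsv(overrep, config$outdir,
                                         "overrep_pro_lnm.tsv")
      }
    } else {
      say("enrich", "no gene set survives the size filter; stage skipped")
    }
  }

  # --- stage: recovery report ----------------------------------------
  recovery <- NULL
  if (!is.null(truth) && length(fits)) {
    recovery <- recovery_report(fits, truth, clusters$lnm)
    for (i in seq_len(nrow(recovery)))
      say("recovery", sprintf(
        "%s: sensitivity %.3f, FP fraction %.4f (%d true, %d null)",
        recovery$outcome[i], recovery$sensitivity[i],
        recovery$fp_fraction[i], recovery$n_true[i],
        recovery$n_null[i]))
    if (!is.null(attr(recovery, "ari")))
      say("recovery", sprintf("LNM cluster ARI vs planted modules: %.3f",
                              attr(recovery, "ari")))
    rec_out <- recovery
    rec_out$cluster_ari <- attr(recovery, "ari") %||% NA_real_
    paths$recovery <- write_stage_tsv(rec_out, config$outdir,
                                      "recovery.tsv")
  }

  writeLines(log_lines, log_path)
  paths$log <- log_path
  invisible(structure(list(fits = fits, clusters = clusters,
                           signatures = signatures, gsea = gsea,
                           overrep = overrep, recovery = recovery,
                           truth = truth, studies = studies,
                           config = config, paths = paths),
                      class = "hnc_pipeline"))
}

#' @export
print.hnc_pipeline <- function(x, ...) {
  cat("hncmeta pipeline run:", x$config$outdir, "\n")
  for (outc in names(x$fits)) print(x$fits[[outc]])
  if (!is.null(x$recovery)) {
    cat("Recovery vs ground truth:\n")
    print(x$recovery, row.names = FALSE)
  }
  invisible(x)
}

# Gene-set collection used by the synthetic enrichment stage: the planted
# co-expression modules as true sets plus seeded random sets as decoys.
reference_collection <- function(universe, truth = NULL, seed = 1L,
                                 n_random = 12L) {
  set.seed(seed)
  sets <- list()
  if (!is.null(truth)) {
    for (m in sort(unique(stats::na.omit(truth$module_id)))) {
      members <- intersect(truth$gene_id[!is.na(truth$module_id) &
                                           truth$module_id == m],
                           universe)
      if (length(members))
        sets[[sprintf("module_%d", m)]] <- members
    }
  }
  for (i in seq_len(n_random)) {
    size <- sample(20:100, 1)
    sets[[sprintf("random_%02d", i)]] <- sample(universe,
                                                min(size,
                                                    length(universe)))
  }
  structure(sets, class = "gene_set_collection")
}
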