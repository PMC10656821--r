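#' Two-pass missingness filter
#'
#' First drops samples (columns) missing values for at least
#' \code{sample_threshold} of genes, then drops genes (rows) missing
#' values for at least \code{gene_threshold} of the remaining samples.
#' Thresholds are inclusive: a sample missing exactly 10% of genes is
#' removed under the default.
#'
#' @param matrix genes/probes x samples numeric matrix, possibly with NA.
#' @param sample_threshold,gene_threshold fractions in (0, 1].
#' @return the filtered matrix.
#' @export
filter_missingness <- function(matrix, sample_threshold = 0.10,
                               gene_threshold = 0.10) {
  check_matrix(matrix)
  stopifnot(sample_threshold > 0, sample_threshold <= 1,
            gene_threshold > 0, gene_threshold <= 1)
  keep_s <- colMeans(is.na(matrix)) < sample_threshold
  matrix <- matrix[, keep_s, drop = FALSE]
  if (ncol(matrix) == 0) stop("no usable data: all samples filtered out")
  keep_g <- rowMeans(is.na(matrix)) < gene_threshold
  matrix <- matrix[keep_g, , drop = FALSE]
  if (nrow(matrix) == 0) stop("no usable data: all genes filtered out")
  matrix
}

#' Quantile normalization
#'
#' Forces every column onto the common distribution whose order statistics
#' are the across-column means of sorted values. Tied entries within a
#' column receive the mean of the reference values over their rank span
#' ("average ties"), so the defining property -- all columns share one
#' value multiset -- holds exactly in the tie-free case and approximately
#' under ties.
#'
#' @param matrix numeric matrix without missing values.
#' @return normalized matrix of the same shape.
#' @examples
#' m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
#' rownames(m) <- paste0("g", 1:3)
#' quantile_normalize(m)  # both columns become (2.5, 3.5, 4.5)
#' @export
quantile_normalize <- function(matrix) {
  check_matrix(matrix)
  if (anyNA(matrix))
    stop("quantile normalization requires a complete matrix")
  ref <- rowMeans(apply(matrix, 2, sort))
  out <- apply(matrix, 2, function(col) {
    tgt <- numeric(length(col))
    tgt[order(col)] <- ref
    stats::ave(tgt, match(col, col), FUN = mean)
  })
  dimnames(out) <- dimnames(matrix)
  out
}

#' Collapse probe-level rows to one row per gene by "maxmean"
#'
#' For each gene, keeps the probe whose mean across all samples is
#' largest; exact ties are broken by the lexicographically smallest probe
#' id, making the collapse deterministic across platforms.
#'
#' @param probe_matrix probes x samples numeric matrix.
#' @param probe_gene_map named character vector, probe id -> gene id,
#'   covering every row of \code{probe_matrix}.
#' @return genes x samples matrix (rows renamed to gene ids), with an
#'   attribute \code{selected_probe} recording the retained probe per
#'   gene.
#' @export
collapse_probes_maxmean <- function(probe_matrix, probe_gene_map) {
  check_matrix(probe_matrix, "probe_matrix")
  probes <- rownames(probe_matrix)
  if (!all(probes %in% names(probe_gene_map)))
    stop("probe_gene_map does not cover every probe")
  gene <- unname(probe_gene_map[probes])
  means <- rowMeans(probe_matrix, na.rm = TRUE)
  ord <- order(gene, -means, probes, method = "radix")
  first <- ord[!duplicated(gene[ord])]
  sel <- probes[sort(first)]
  out <- probe_matrix[sel, , drop = FALSE]
  rownames(out) <- gene[match(sel, probes)]
  attr(out, "selected_probe") <- stats::setNames(sel, rownames(out))
  out
}

#' Log2 transform with explicit scale flag
#'
#' Applies \code{log2(x + offset)} when the data are on the linear scale;
#' identity when \code{already_log} is \code{TRUE}. The scale is declared,
#' not guessed; [guess_log_scale()] offers a heuristic for callers who
#' want one.
#'
#' @param matrix numeric matrix; nonnegative when \code{already_log} is
#'   \code{FALSE}.
#' @param already_log is the matrix already in log2 space?
#' @param offset pseudo-value added before the log (default 1).
#' @return transformed matrix.
#' @export
log2_transform <- function(matrix, already_log = FALSE, offset = 1) {
  check_matrix(matrix)
  if (already_log) return(matrix)
  if (any(matrix < 0, na.rm = TRUE))
    stop("negative values on the linear scale")
  log2(matrix + offset)
}

#' Heuristic linear-vs-log2 scale detector
#'
#' @param matrix numeric matrix.
#' @param linear_max values above this suggest linear scale (default 50).
#' @return \code{TRUE} if the matrix looks already log2-transformed.
#' @export
guess_log_scale <- function(matrix, linear_max = 50) {
  max(matrix, na.rm = TRUE) <= linear_max
}

#' Per-gene standardization to standard expression scores
#'
#' Each gene row is centered and scaled within the study:
#' \code{(x - mean) / sd}, with the sample (n-1) standard deviation.
#' Missing entries are excluded from the mean/SD and stay missing.
#' Zero-variance genes cannot be standardized and are dropped with a
#' warning.
#'
#' @param matrix genes x samples numeric matrix.
#' @return standardized matrix; every complete row has mean 0 and sample
#'   SD 1.
#' @export
standardize_genes <- function(matrix) {
  check_matrix(matrix)
  mu <- rowMeans(matrix, na.rm = TRUE)
  sdv <- apply(matrix, 1, stats::sd, na.rm = TRUE)
  bad <- !is.finite(sdv) | sdv == 0
  if (any(bad)) {
    warning(sum(bad), " zero-variance gene(s) excluded from standardization: ",
            paste(utils::head(rownames(matrix)[bad], 5), collapse = ", "))
    matrix <- matrix[!bad, , drop = FALSE]
    mu <- mu[!bad]
    sdv <- sdv[!bad]
  }
  if (nrow(matrix) == 0) stop("no genes left after removing zero variance")
  (matrix - mu) / sdv
}

#' Sex-concordance QC from XIST and RPS4Y1 expression
#'
#' Infers each sample's sex from the log2 expression difference
#' XIST - RPS4Y1 (female when positive) and reports the fraction of
#' annotated samples whose inferred sex disagrees. A high discordance
#' fraction flags mislabeled clinical data.
#'
#' @param matrix genes x samples matrix on the log2 (or standardized)
#'   scale containing rows \code{XIST} and \code{RPS4Y1}.
#' @param clinical data.frame with \code{sample_id} and \code{sex}
#'   (\code{"male"}/\code{"female"}, NA allowed) matching the columns.
#' @return list with \code{inferred_sex} (named character vector),
#'   \code{discordant} (named logical over annotated samples) and
#'   \code{discordance_fraction}; \code{NULL} with a warning when a marker
#'   gene is absent.
#' @export
check_sex_concordance <- function(matrix, clinical) {
  check_matrix(matrix)
  if (!all(c("XIST", "RPS4Y1") %in% rownames(matrix))) {
    warning("XIST/RPS4Y1 not present; sex-concordance QC skipped")
    return(NULL)
  }
  inferred <- ifelse(matrix["XIST", ] - matrix["RPS4Y1", ] > 0,
                     "female", "male")
  names(inferred) <- colnames(matrix)
  annotated <- clinical[!is.na(clinical$sex), , drop = FALSE]
  annotated <- annotated[annotated$sample_id %in% names(inferred), ,
                         drop = FALSE]
  if (nrow(annotated) == 0) {
    return(list(inferred_sex = inferred, discordant = logical(0),
                discordance_fraction = NA_real_))
  }
  disc <- inferred[annotated$sample_id] != annotated$sex
  list(inferred_sex = inferred,
       discordant = disc,
       discordance_fraction = mean(disc))
}

#' Harmonize one cohort to a standardized study dataset
#'
#' Runs the per-study preprocessing chain in the fixed order: missingness
#' filter (samples, then genes), quantile normalization, maxmean probe
#' collapse, log2 transform, per-gene standardization. Returns the
#' analysis-ready study object whose expression columns correspond
#' one-to-one to clinical rows.
#'
#' @param cohort list with \code{probe_matrix}, \code{probe_gene_map},
#'   \code{clinical}, \code{study_id} (the shape written/read by
#'   [write_compendium()]/[read_cohort()]).
#' @param already_log is the probe matrix already log2-scale?
#' @param sample_threshold,gene_threshold missingness thresholds passed to
#'   [filter_missingness()].
#' @return object of class \code{study_dataset}: \code{expression}
#'   (standardized genes x samples), \code{clinical}, \code{study_id},
#'   \code{n_samples}, \code{sex_qc}.
#' @export
harmonize_study <- function(cohort, already_log = FALSE,
                            sample_threshold = 0.10,
                            gene_threshold = 0.10) {
  m <- filter_missingness(cohort$probe_matrix, sample_threshold,
                          gene_threshold)
  complete <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(complete) == 0) stop("no complete probes to normalize")
  m <- quantile_normalize(complete)
  m <- collapse_probes_maxmean(m, cohort$probe_gene_map)
  m <- log2_transform(m, already_log = already_log)
  sex_qc <- suppressWarnings(check_sex_concordance(m, cohort$clinical))
  m <- suppressWarnings(standardize_genes(m))
  clinical <- cohort$clinical[match(colnames(m),
                                    cohort$clinical$sample_id), ,
                              drop = FALSE]
  if (anyNA(clinical$sample_id))
    stop("expression columns without clinical rows in ", cohort$study_id)
  structure(list(expression = m,
                 clinical = clinical,
                 study_id = cohort$study_id,
                 n_samples = ncol(m),
                 sex_qc = sex_qc),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("Study %s: %d genes x %d samples (standardized)\n",
              x$study_id, nrow(x$expression), x$n_samples))
  if (!is.null(x$sex_qc) && is.finite(x$sex_qc$discordance_fraction))
    cat(sprintf("  sex-concordance QC: %.1f%% discordant\n",
                100 * x$sex_qc$discordance_fraction))
  invisible(x)
}

#' Assemble a complete cross-study matrix for clustering
#'
#' Restricts each study to samples with observed data for at least
#' \code{coverage} of \code{gene_list} (genes a study does not measure
#' count as missing for all its samples), concatenates the retained
#' samples column-wise over \code{gene_list}, and keeps only genes with
#' complete data across every retained sample.
#'
#' @param studies list of \code{study_dataset} objects.
#' @param gene_list character vector of genes of interest (e.g. the
#'   prognostic genes).
#' @param coverage per-sample coverage rule (default 0.80).
#' @return matrix (complete genes x retained samples) with attributes
#'   \code{n_input_genes}, \code{n_complete_genes}, \code{retention_pct}
#'   (rounded half-up), \code{samples_per_study}.
#' @export
assemble_complete_matrix <- function(studies, gene_list, coverage = 0.80) {
  stopifnot(length(gene_list) > 0, coverage > 0, coverage <= 1)
  blocks <- list()
  kept <- integer(0)
  for (st in studies) {
    expr <- st$expression
    sub <- matrix(NA_real_, nrow = length(gene_list), ncol = ncol(expr),
                  dimnames = list(gene_list, colnames(expr)))
    common <- intersect(gene_list, rownames(expr))
    sub[common, ] <- expr[common, , drop = FALSE]
    frac <- colMeans(!is.na(sub))
    keep <- frac >= coverage
    kept[st$study_id] <- sum(keep)
    if (any(keep))
      blocks[[st$study_id]] <- sub[, keep, drop = FALSE]
  }
  if (!length(blocks))
    stop(sprintf("no sample meets the %.0f%% coverage rule in any of %d studies",
                 100 * coverage, length(studies)))
  combined <- do.call(cbind, blocks)
  complete <- combined[stats::complete.cases(combined), , drop = FALSE]
  if (nrow(complete) == 0)
    stop(sprintf("no gene has complete data across the %d retained samples",
                 ncol(combined)))
  attr(complete, "n_input_genes") <- length(gene_list)
  attr(complete, "n_complete_genes") <- nrow(complete)
  attr(complete, "retention_pct") <- pct(nrow(complete), length(gene_list))
  attr(complete, "samples_per_study") <- kept
  complete
}
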