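#' Thresholds governing gene classification and study eligibility
#'
#' Collects every numeric policy constant of the meta-analysis in one
#' object: the meta-z significance cutoff (3.09, the upper standard-normal
#' quantile at p = 0.001 rounded to two decimals), the minimum number of
#' studies a gene must appear in to be combined (2 for survival and grade;
#' at least half of all studies for lymph-node metastasis), the per-study
#' sample floors (20 samples with survival data; 5 per LNM group; 10
#' complete cases for covariate-adjusted models), and the 80% per-sample
#' gene-coverage rule used when assembling the complete matrix for
#' clustering.
#'
#' @param z_threshold meta-z cutoff for calling a gene prognostic
#'   (inclusive: |meta-z| >= threshold).
#' @param min_studies_survival minimum studies per gene, survival outcome.
#' @param min_study_fraction_lnm minimum fraction of eligible studies a
#'   gene must be measured in for the LNM meta-analysis.
#' @param min_studies_grade minimum studies per gene, grade outcome.
#' @param survival_floor minimum samples with survival data per study.
#' @param lnm_group_floor minimum samples in each LNM group per study.
#' @param adjusted_floor minimum complete cases for adjusted models.
#' @param clustering_coverage per-sample fraction of genes that must be
#'   observed for a sample to enter the clustering matrix.
#' @return an object of class \code{threshold_policy} (a named list).
#' @examples
#' threshold_policy()
#' @export
threshold_policy <- function(z_threshold = 3.09,
                             min_studies_survival = 2L,
                             min_study_fraction_lnm = 0.5,
                             min_studies_grade = 2L,
                             survival_floor = 20L,
                             lnm_group_floor = 5L,
                             adjusted_floor = 10L,
                             clustering_coverage = 0.80) {
  stopifnot(z_threshold > 0, min_studies_survival >= 1,
            min_study_fraction_lnm > 0, min_study_fraction_lnm <= 1,
            min_studies_grade >= 1, survival_floor >= 2,
            lnm_group_floor >= 2, adjusted_floor >= 2,
            clustering_coverage > 0, clustering_coverage <= 1)
  structure(list(z_threshold = z_threshold,
                 min_studies_survival = as.integer(min_studies_survival),
                 min_study_fraction_lnm = min_study_fraction_lnm,
                 min_studies_grade = as.integer(min_studies_grade),
                 survival_floor = as.integer(survival_floor),
                 lnm_group_floor = as.integer(lnm_group_floor),
                 adjusted_floor = as.integer(adjusted_floor),
                 clustering_coverage = clustering_coverage),
            class = "threshold_policy")
}

#' @export
print.threshold_policy <- function(x, ...) {
  cat("Meta-analysis threshold policy\n")
  cat(sprintf("  |meta-z| cutoff:            %.2f\n", x$z_threshold))
  cat(sprintf("  min studies (survival):     %d\n", x$min_studies_survival))
  cat(sprintf("  min study fraction (LNM):   %.2f\n", x$min_study_fraction_lnm))
  cat(sprintf("  min studies (grade):        %d\n", x$min_studies_grade))
  cat(sprintf("  survival sample floor:      %d\n", x$survival_floor))
  cat(sprintf("  LNM per-group floor:        %d\n", x$lnm_group_floor))
  cat(sprintf("  adjusted-model case floor:  %d\n", x$adjusted_floor))
  cat(sprintf("  clustering coverage rule:   %.2f\n", x$clustering_coverage))
  invisible(x)
}

#' The meta-z significance threshold from a tail probability
#'
#' @param p one-sided tail probability (default 0.001).
#' @param digits decimals to round to (default 2).
#' @return the upper standard-normal quantile at \code{p}, rounded.
#' @examples
#' meta_z_threshold()  # 3.09
#' @export
meta_z_threshold <- function(p = 0.001, digits = 2) {
  round_half_up(stats::qnorm(1 - p), digits)
}
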