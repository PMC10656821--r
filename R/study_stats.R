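# Mesenchymal and epithelial marker genes used by the EMT score.
EMT_MESENCHYMAL <- c("VIM", "CDH2", "FOXC2", "SNAI1", "SNAI2", "TWIST1",
                     "GSC", "FN1", "ITGB6", "MMP2", "MMP3", "MMP9", "SOX10")
EMT_EPITHELIAL <- c("CDH1", "DSP", "TJP1")

new_gene_assoc <- function(gene_id, study_id, stat_kind, effect, se, z, n,
                           extra = NULL) {
  out <- data.frame(gene_id = gene_id, study_id = study_id,
                    stat_kind = stat_kind, effect = effect, se = se,
                    z = z, n = as.integer(n), stringsAsFactors = FALSE)
  if (!is.null(extra)) out <- cbind(out, extra)
  out
}

#' Per-gene Cox proportional-hazards z-score
#'
#' Univariate Cox regression of survival on one standardized expression
#' vector; the returned z is the Wald statistic (coefficient / SE), so
#' positive z means higher expression is associated with higher hazard
#' (worse survival). Tied event times use the Efron approximation.
#'
#' @param expr per-sample standardized expression.
#' @param time_months positive follow-up times.
#' @param event 0/1 event indicators.
#' @param gene_id,study_id labels carried into the result.
#' @param floor minimum number of samples with outcome data (default 20,
#'   the study-inclusion floor for the survival meta-analysis).
#' @return one-row data.frame (gene/study association record), or
#'   \code{NULL} with a message when the fit is skipped (zero variance,
#'   fewer than 2 events, below the floor, or monotone likelihood).
#' @export
cox_z <- function(expr, time_months, event, gene_id = "gene",
                  study_id = "study", floor = 20L) {
  ok <- is.finite(expr) & is.finite(time_months) & !is.na(event)
  expr <- expr[ok]; time_months <- time_months[ok]; event <- event[ok]
  n <- length(expr)
  if (n < floor) stop("fewer than ", floor, " samples with survival data")
  if (any(time_months <= 0)) stop("survival times must be positive")
  if (sum(event) < 2) stop("fewer than 2 events")
  if (stats::sd(expr) == 0) stop("zero-variance expression")
  fit <- survival::coxph.fit(matrix(expr, ncol = 1),
                             survival::Surv(time_months, event),
                             strata = NULL, offset = NULL, init = 0,
                             control = survival::coxph.control(),
                             weights = NULL, method = "efron",
                             rownames = NULL)
  beta <- unname(fit$coefficients)
  se <- sqrt(fit$var[1, 1])
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15) {
    message("cox_z: monotone likelihood for ", gene_id, " in ", study_id,
            "; gene skipped")
    return(NULL)
  }
  new_gene_assoc(gene_id, study_id, "cox_z", beta, se, beta / se, n)
}

#' Standardized mean difference in expression between LNM groups
#'
#' Cohen's d between LNM-positive and LNM-negative samples using the
#' pooled standard deviation, with the large-sample variance
#' \code{v = (n1 + n0) / (n1 n0) + d^2 / (2 (n1 + n0))} and
#' \code{z = d / sqrt(v)}. Positive d means higher expression in LNM+.
#' An optional Hedges small-sample correction multiplies d by
#' \code{1 - 3 / (4 (n1 + n0) - 9)}.
#'
#' @param expr per-sample standardized expression.
#' @param lnm_status 0/1 per sample (NA allowed, dropped).
#' @param gene_id,study_id labels.
#' @param group_floor minimum samples per group (default 5, the
#'   study-inclusion floor for the LNM meta-analysis).
#' @param hedges apply the Hedges g correction (default \code{FALSE}).
#' @return one-row data.frame including group means/SDs/sizes and the
#'   variance \code{v}.
#' @export
smd_lnm <- function(expr, lnm_status, gene_id = "gene",
                    study_id = "study", group_floor = 5L, hedges = FALSE) {
  ok <- is.finite(expr) & !is.na(lnm_status)
  expr <- expr[ok]; lnm_status <- lnm_status[ok]
  x1 <- expr[lnm_status == 1]
  x0 <- expr[lnm_status == 0]
  n1 <- length(x1); n0 <- length(x0)
  if (n1 < group_floor || n0 < group_floor)
    stop("fewer than ", group_floor, " samples in an LNM group")
  s1 <- stats::sd(x1); s0 <- stats::sd(x0)
  sp2 <- ((n1 - 1) * s1^2 + (n0 - 1) * s0^2) / (n1 + n0 - 2)
  if (sp2 == 0) stop("both groups constant: SMD undefined")
  d <- (mean(x1) - mean(x0)) / sqrt(sp2)
  if (hedges) d <- d * (1 - 3 / (4 * (n1 + n0) - 9))
  v <- (n1 + n0) / (n1 * n0) + d^2 / (2 * (n1 + n0))
  new_gene_assoc(gene_id, study_id, "lnm_smd", d, sqrt(v), d / sqrt(v),
                 n1 + n0,
                 extra = data.frame(mean1 = mean(x1), sd1 = s1, n1 = n1,
                                    mean0 = mean(x0), sd0 = s0, n0 = n0,
                                    v = v))
}

#' Per-gene association with ordinal tumor grade
#'
#' Simple linear regression of expression on grade coded numerically 1-4;
#' z is the slope t-statistic, so positive z means higher expression at
#' higher (less differentiated) grade. For simple regression the
#' t-statistic is symmetric in which variable is the response, so the
#' choice is inconsequential.
#'
#' @param expr per-sample standardized expression.
#' @param grade ordinal 1-4 per sample (NA allowed, dropped).
#' @param gene_id,study_id labels.
#' @return one-row data.frame with the slope, its SE, and z.
#' @export
grade_z <- function(expr, grade, gene_id = "gene", study_id = "study") {
  ok <- is.finite(expr) & !is.na(grade)
  expr <- expr[ok]; grade <- as.numeric(grade[ok])
  n <- length(expr)
  if (n < 3) stop("fewer than 3 samples with grade data")
  if (length(unique(grade)) < 2) stop("a single grade level observed")
  if (stats::sd(expr) == 0) stop("zero-variance expression")
  r <- stats::cor(expr, grade)
  slope <- r * stats::sd(expr) / stats::sd(grade)
  se <- sqrt((1 - r^2) / (n - 2)) * stats::sd(expr) / stats::sd(grade)
  tval <- if (se == 0) sign(slope) * Inf else slope / se
  new_gene_assoc(gene_id, study_id, "grade_z", slope, se, tval, n)
}

#' Per-sample signature score
#'
#' The arithmetic mean of standardized expression over the signature
#' genes present in the matrix. When fewer than 80% of signature genes
#' are present a warning is issued; the score is still the mean over the
#' available genes.
#'
#' @param matrix standardized genes x samples matrix.
#' @param signature character vector of gene ids.
#' @param name signature label.
#' @return data.frame: \code{sample_id}, \code{signature_name},
#'   \code{score}, \code{n_genes_used}, \code{n_genes_in_signature}.
#' @export
signature_score <- function(matrix, signature, name = "signature") {
  check_matrix(matrix)
  present <- intersect(signature, rownames(matrix))
  if (!length(present)) stop("no signature genes present in matrix")
  if (length(present) < 0.8 * length(signature))
    warning(sprintf("signature '%s': only %d/%d genes present",
                    name, length(present), length(signature)))
  score <- colMeans(matrix[present, , drop = FALSE], na.rm = TRUE)
  data.frame(sample_id = colnames(matrix),
             signature_name = name,
             score = unname(score),
             n_genes_used = length(present),
             n_genes_in_signature = length(signature),
             stringsAsFactors = FALSE)
}

#' Epithelial-to-mesenchymal transition (EMT) score
#'
#' Sum of normalized counts over 13 mesenchymal marker genes minus the
#' sum over 3 epithelial markers (CDH1, DSP, TJP1). Genes absent from the
#' matrix contribute 0 with a warning.
#'
#' @param matrix normalized counts, genes x samples.
#' @return named numeric vector of per-sample EMT scores.
#' @export
emt_score <- function(matrix) {
  check_matrix(matrix)
  missing <- setdiff(c(EMT_MESENCHYMAL, EMT_EPITHELIAL), rownames(matrix))
  if (length(missing))
    warning("EMT genes absent (contribute 0): ",
            paste(missing, collapse = ", "))
  sum_over <- function(genes) {
    present <- intersect(genes, rownames(matrix))
    if (!length(present)) return(rep(0, ncol(matrix)))
    colSums(matrix[present, , drop = FALSE])
  }
  stats::setNames(sum_over(EMT_MESENCHYMAL) - sum_over(EMT_EPITHELIAL),
                  colnames(matrix))
}

#' Covariate-adjusted association of a signature score with an outcome
#'
#' Cox regression (survival) or logistic regression (LNM) of the outcome
#' on the signature score plus covariates (typically HPV status). Only
#' samples with complete data enter; a study below the 10-complete-case
#' eligibility floor is excluded (returns \code{NULL} with a message).
#'
#' @param score per-sample numeric signature score.
#' @param clinical data.frame aligned with \code{score}; must carry
#'   \code{time_months}/\code{event} for survival or \code{lnm_status}
#'   for LNM, plus the covariate columns.
#' @param outcome \code{"survival"} or \code{"lnm"}.
#' @param covariates character vector of clinical column names (default
#'   \code{"hpv_status"}).
#' @param floor minimum complete cases (default 10).
#' @param study_id label.
#' @return one-row data.frame with the Wald z of the score term,
#'   its coefficient and SE, \code{n}, and a \code{separation} flag
#'   (logistic only), or \code{NULL} when ineligible.
#' @export
adjusted_assoc <- function(score, clinical,
                           outcome = c("survival", "lnm"),
                           covariates = "hpv_status", floor = 10L,
                           study_id = "study") {
  outcome <- match.arg(outcome)
  need <- c(if (outcome == "survival") c("time_months", "event")
            else "lnm_status", covariates)
  miss <- setdiff(need, names(clinical))
  if (length(miss)) stop("clinical table lacks columns: ",
                         paste(miss, collapse = ", "))
  df <- cbind(data.frame(.score = score), clinical[, need, drop = FALSE])
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < floor) {
    message(sprintf("study %s excluded: %d < %d complete cases",
                    study_id, nrow(df), floor))
    return(NULL)
  }
  rhs <- paste(c(".score", covariates), collapse = " + ")
  separation <- FALSE
  if (outcome == "survival") {
    fit <- survival::coxph(stats::as.formula(
      paste("survival::Surv(time_months, event) ~", rhs)), data = df)
    co <- summary(fit)$coefficients
    est <- co[".score", "coef"]; se <- co[".score", "se(coef)"]
  } else {
    fit <- withCallingHandlers(
      stats::glm(stats::as.formula(paste("lnm_status ~", rhs)),
                 family = stats::binomial(), data = df),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w)))
          separation <<- TRUE
        invokeRestart("muffleWarning")
      })
    co <- summary(fit)$coefficients
    est <- co[".score", "Estimate"]; se <- co[".score", "Std. Error"]
  }
  data.frame(study_id = study_id, outcome = outcome, effect = est,
             se = se, z = est / se, n = nrow(df),
             separation = separation, stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum comparison of a score between two groups
#'
#' Two-sided exact Wilcoxon rank-sum p-value when both groups have at
#' most 25 observations and there are no ties; normal approximation with
#' continuity correction otherwise. When covariates are supplied, a
#' linear model \code{score ~ group + covariates} additionally reports
#' the adjusted group coefficient and its p-value.
#'
#' @param score numeric values.
#' @param group binary group labels (two levels, both nonempty).
#' @param covariates optional data.frame of covariates.
#' @return list with \code{wilcoxon_p}, \code{exact}, and when covariates
#'   are given \code{adjusted_coef}, \code{adjusted_p}.
#' @examples
#' compare_groups(c(1, 2, 3, 4, 5, 6), c(0, 0, 0, 1, 1, 1))$wilcoxon_p
#' @export
compare_groups <- function(score, group, covariates = NULL) {
  ok <- is.finite(score) & !is.na(group)
  score <- score[ok]; group <- group[ok]
  lev <- unique(group)
  if (length(lev) != 2) stop("group must have exactly 2 nonempty levels")
  x <- score[group == lev[1]]
  y <- score[group == lev[2]]
  use_exact <- length(x) <= 25 && length(y) <= 25 &&
    !anyDuplicated(score)
  wt <- stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)
  out <- list(wilcoxon_p = wt$p.value, exact = use_exact)
  if (!is.null(covariates)) {
    df <- data.frame(.score = score, .group = as.numeric(group == lev[2]),
                     covariates[ok, , drop = FALSE])
    fit <- stats::lm(.score ~ ., data = df)
    co <- summary(fit)$coefficients
    out$adjusted_coef <- co[".group", "Estimate"]
    out$adjusted_p <- co[".group", "Pr(>|t|)"]
  }
  out
}

#' All per-gene association statistics for one study
#'
#' Applies [cox_z()], [smd_lnm()] or [grade_z()] to every gene of a
#' harmonized study. Genes whose fit is skipped (zero variance, monotone
#' likelihood) are silently absent from the result; a study that fails
#' the outcome's eligibility floor returns \code{NULL} with a message.
#'
#' @param study a \code{study_dataset}.
#' @param outcome \code{"survival"}, \code{"lnm"} or \code{"grade"}.
#' @param policy a [threshold_policy()].
#' @return data.frame of per-gene association records, or \code{NULL}.
#' @export
study_assoc <- function(study, outcome = c("survival", "lnm", "grade"),
                        policy = threshold_policy()) {
  outcome <- match.arg(outcome)
  expr <- study$expression
  cl <- study$clinical
  if (outcome == "survival") {
    ok <- is.finite(cl$time_months) & !is.na(cl$event)
    if (sum(ok) < policy$survival_floor || sum(cl$event[ok]) < 2) {
      message(sprintf("study %s ineligible for survival analysis (n=%d)",
                      study$study_id, sum(ok)))
      return(NULL)
    }
    y <- survival::Surv(cl$time_months[ok], cl$event[ok])
    sub <- expr[, ok, drop = FALSE]
    ctrl <- survival::coxph.control()
    genes <- rownames(sub)
    beta <- se <- rep(NA_real_, length(genes))
    for (i in seq_along(genes)) {
      x <- sub[i, ]
      if (stats::sd(x) == 0) next
      fit <- survival::coxph.fit(matrix(x, ncol = 1), y, strata = NULL,
                                 offset = NULL, init = 0, control = ctrl,
                                 weights = NULL, method = "efron",
                                 rownames = NULL)
      b <- unname(fit$coefficients); s <- sqrt(fit$var[1, 1])
      if (is.finite(b) && is.finite(s) && abs(b) <= 15) {
        beta[i] <- b; se[i] <- s
      }
    }
    keep <- is.finite(beta)
    if (!any(keep)) return(NULL)
    return(new_gene_assoc(genes[keep], study$study_id, "cox_z",
                          beta[keep], se[keep], beta[keep] / se[keep],
                          sum(ok)))
  } else if (outcome == "lnm") {
    ok <- !is.na(cl$lnm_status)
    n1 <- sum(cl$lnm_status[ok] == 1); n0 <- sum(cl$lnm_status[ok] == 0)
    if (n1 < policy$lnm_group_floor || n0 < policy$lnm_group_floor) {
      message(sprintf("study %s ineligible for LNM analysis (%d LNM+, %d LNM0)",
                      study$study_id, n1, n0))
      return(NULL)
    }
    lnm <- cl$lnm_status[ok]
    sub <- expr[, ok, drop = FALSE]
    # vectorized Cohen's d across all genes; matches smd_lnm() per gene
    x1 <- sub[, lnm == 1, drop = FALSE]
    x0 <- sub[, lnm == 0, drop = FALSE]
    m1 <- rowMeans(x1); m0 <- rowMeans(x0)
    s1sq <- rowSums((x1 - m1)^2) / (n1 - 1)
    s0sq <- rowSums((x0 - m0)^2) / (n0 - 1)
    sp2 <- ((n1 - 1) * s1sq + (n0 - 1) * s0sq) / (n1 + n0 - 2)
    keep <- sp2 > 0
    if (!any(keep)) return(NULL)
    d <- (m1[keep] - m0[keep]) / sqrt(sp2[keep])
    v <- (n1 + n0) / (n1 * n0) + d^2 / (2 * (n1 + n0))
    return(new_gene_assoc(rownames(sub)[keep], study$study_id, "lnm_smd",
                          d, sqrt(v), d / sqrt(v), n1 + n0,
                          extra = data.frame(mean1 = m1[keep],
                                             sd1 = sqrt(s1sq[keep]),
                                             n1 = n1,
                                             mean0 = m0[keep],
                                             sd0 = sqrt(s0sq[keep]),
                                             n0 = n0, v = v)))
  } else {
    ok <- !is.na(cl$grade)
    if (sum(ok) < 3 || length(unique(cl$grade[ok])) < 2) {
      message(sprintf("study %s ineligible for grade analysis",
                      study$study_id))
      return(NULL)
    }
    grd <- as.numeric(cl$grade[ok])
    sub <- expr[, ok, drop = FALSE]
    # vectorized simple regression of expression on grade; matches grade_z()
    n <- length(grd)
    sd_e <- sqrt(rowSums((sub - rowMeans(sub))^2) / (n - 1))
    keep <- sd_e > 0
    if (!any(keep)) return(NULL)
    r <- as.vector(stats::cor(t(sub[keep, , drop = FALSE]), grd))
    slope <- r * sd_e[keep] / stats::sd(grd)
    se <- sqrt(pmax(1 - r^2, 0) / (n - 2)) * sd_e[keep] / stats::sd(grd)
    tval <- ifelse(se == 0, sign(slope) * Inf, slope / se)
    return(new_gene_assoc(rownames(sub)[keep], study$study_id, "grade_z",
                          slope, se, tval, n))
  }
}
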