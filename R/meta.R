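#' Liptak's weighted (Stouffer) meta-z combination
#'
#' Combines per-study z-scores with weights equal to the square roots of
#' the study sample sizes:
#' \deqn{Z = \sum_i \sqrt{n_i} z_i / \sqrt{\sum_i n_i}.}
#' Studies in which a gene is not measured are simply absent from the
#' input vectors.
#'
#' @param z per-study z-scores.
#' @param n per-study sample sizes (> 0), same length as \code{z}.
#' @return the combined meta-z.
#' @examples
#' liptak_meta_z(c(3, 0), c(100, 25))  # (10*3 + 5*0)/sqrt(125)
#' @export
liptak_meta_z <- function(z, n) {
  if (!length(z) || length(z) != length(n))
    stop("z and n must be nonempty vectors of equal length")
  if (any(n <= 0)) stop("sample sizes must be positive")
  sum(sqrt(n) * z) / sqrt(sum(n))
}

#' DerSimonian-Laird random-effects pooling of effect sizes
#'
#' Moment estimator of the between-study variance: with fixed-effect
#' weights \eqn{w_i = 1/v_i} and \eqn{Q = \sum w_i (d_i - \bar d)^2},
#' \eqn{\tau^2 = \max(0, (Q - (k-1)) / (\sum w - \sum w^2 / \sum w))};
#' random-effects weights \eqn{w_i^* = 1/(v_i + \tau^2)} then give the
#' pooled effect, its standard error \eqn{1/\sqrt{\sum w^*}}, and
#' meta-z = pooled / SE. A single study passes through unchanged with
#' \eqn{\tau^2 = 0}.
#'
#' @param d per-study effect sizes (standardized mean differences).
#' @param v per-study variances (> 0).
#' @return list: \code{pooled}, \code{se}, \code{tau2}, \code{q_stat},
#'   \code{meta_z}, \code{k}.
#' @examples
#' dl_random_effects(c(0.2, 0.8), c(0.05, 0.05))
#' @export
dl_random_effects <- function(d, v) {
  if (!length(d) || length(d) != length(v))
    stop("d and v must be nonempty vectors of equal length")
  if (any(v <= 0)) stop("variances must be positive")
  k <- length(d)
  w <- 1 / v
  d_fixed <- sum(w * d) / sum(w)
  q <- sum(w * (d - d_fixed)^2)
  tau2 <- if (k == 1) 0 else {
    denom <- sum(w) - sum(w^2) / sum(w)
    max(0, (q - (k - 1)) / denom)
  }
  w_star <- 1 / (v + tau2)
  pooled <- sum(w_star * d) / sum(w_star)
  se <- 1 / sqrt(sum(w_star))
  list(pooled = pooled, se = se, tau2 = tau2, q_stat = q,
       meta_z = pooled / se, k = k)
}

#' Classify genes as prognostic from their meta-z scores
#'
#' Applies the inclusive |meta-z| >= 3.09 rule (p < 0.001 per tail) after
#' the per-outcome eligibility rules: a gene must be measured in at least
#' 2 studies (survival, grade) or in at least half of the eligible
#' studies (LNM). Orientation of the labels follows the field's naming:
#' for survival, "anti" marks adverse genes (meta-z >= threshold: higher
#' expression, higher hazard) and "pro" favorable genes
#' (meta-z <= -threshold); for LNM and grade, "pro" marks positive
#' association (meta-z >= threshold).
#'
#' @param meta data.frame with columns \code{meta_z} and
#'   \code{n_studies}.
#' @param outcome \code{"survival"}, \code{"lnm"} or \code{"grade"}.
#' @param policy a [threshold_policy()].
#' @param n_total_studies number of eligible studies (required for the
#'   LNM half-of-studies rule).
#' @return \code{meta} with a \code{label} column in
#'   \code{c("pro", "anti", "ns")}.
#' @export
classify_genes <- function(meta, outcome = c("survival", "lnm", "grade"),
                           policy = threshold_policy(),
                           n_total_studies = NULL) {
  outcome <- match.arg(outcome)
  stopifnot(all(c("meta_z", "n_studies") %in% names(meta)))
  eligible <- switch(outcome,
    survival = meta$n_studies >= policy$min_studies_survival,
    grade = meta$n_studies >= policy$min_studies_grade,
    lnm = {
      if (is.null(n_total_studies))
        stop("n_total_studies is required for the LNM eligibility rule")
      meta$n_studies >= policy$min_study_fraction_lnm * n_total_studies
    })
  th <- policy$z_threshold
  label <- rep("ns", nrow(meta))
  if (outcome == "survival") {
    label[eligible & meta$meta_z >= th] <- "anti"
    label[eligible & meta$meta_z <= -th] <- "pro"
  } else {
    label[eligible & meta$meta_z >= th] <- "pro"
    label[eligible & meta$meta_z <= -th] <- "anti"
  }
  meta$label <- label
  meta$eligible <- eligible
  meta
}

#' Overlap between two gene sets with a printed percentage
#'
#' @param a,b character vectors of gene ids (\code{a} nonempty).
#' @return list: \code{n_a}, \code{n_b}, \code{n_overlap},
#'   \code{pct_of_a} (integer percent of \code{a} overlapping \code{b},
#'   rounded half-up).
#' @examples
#' summarize_overlap(letters[1:4], letters[3:6])  # 2/4 = 50%
#' @export
summarize_overlap <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a)) stop("set A is empty")
  k <- length(intersect(a, b))
  list(n_a = length(a), n_b = length(b), n_overlap = k,
       pct_of_a = pct(k, length(a)))
}

#' Cohort outcome summary in the printed style of the study table
#'
#' Counts censored and event samples with the integer percentage of
#' events, and LNM0/LNM+ samples with the percentage LNM+, percentages
#' rounded half-up.
#'
#' @param clinical data.frame with (any of) \code{time_months},
#'   \code{event}, \code{lnm_status}.
#' @return list: \code{n_censored}, \code{n_event}, \code{pct_event},
#'   \code{n_lnm0}, \code{n_lnm_pos}, \code{pct_lnm_pos} (NA when the
#'   outcome is absent).
#' @export
summarize_cohort <- function(clinical) {
  out <- list(n_censored = NA_integer_, n_event = NA_integer_,
              pct_event = NA_real_, n_lnm0 = NA_integer_,
              n_lnm_pos = NA_integer_, pct_lnm_pos = NA_real_)
  if (all(c("time_months", "event") %in% names(clinical))) {
    ev <- clinical$event[!is.na(clinical$event) &
                           !is.na(clinical$time_months)]
    out$n_censored <- sum(ev == 0)
    out$n_event <- sum(ev == 1)
    out$pct_event <- if (length(ev)) pct(sum(ev == 1), length(ev)) else 0
  }
  if ("lnm_status" %in% names(clinical)) {
    ln <- clinical$lnm_status[!is.na(clinical$lnm_status)]
    out$n_lnm0 <- sum(ln == 0)
    out$n_lnm_pos <- sum(ln == 1)
    out$pct_lnm_pos <- if (length(ln)) pct(sum(ln == 1), length(ln))
                       else NA_real_
  }
  out
}

#' Cross-study meta-analysis of gene-outcome associations
#'
#' The central fit: computes per-study, per-gene association statistics
#' (Cox z for survival, standardized mean difference for LNM, ordinal
#' regression z for grade) across a list of harmonized studies, combines
#' them per gene into a meta-z -- Liptak's weighted z for survival and
#' grade, DerSimonian-Laird random effects for LNM -- and classifies
#' genes at the |meta-z| >= 3.09 threshold.
#'
#' @param studies list of \code{study_dataset} objects (see
#'   [harmonize_study()]).
#' @param outcome \code{"survival"}, \code{"lnm"} or \code{"grade"}.
#' @param policy a [threshold_policy()].
#' @param lnm_weighting \code{"dl"} (DerSimonian-Laird inverse-variance
#'   random effects, the default) or \code{"sqrt_n"} (Liptak sqrt-n
#'   weighting of the per-study SMD z-scores, for sensitivity analysis).
#' @return an object of class \code{hnc_meta} with components
#'   \code{results} (per-gene data.frame: \code{gene_id}, \code{meta_z},
#'   \code{pooled_effect}, \code{se}, \code{tau2}, \code{q_stat},
#'   \code{n_studies}, \code{n_total}, \code{label}), \code{per_study}
#'   (the per-study association tables), \code{outcome}, \code{policy},
#'   \code{studies} (ids and sizes of eligible studies), \code{call}.
#' @seealso [classify_genes()], [liptak_meta_z()], [dl_random_effects()]
#' @export
hnc_meta <- function(studies, outcome = c("survival", "lnm", "grade"),
                     policy = threshold_policy(),
                     lnm_weighting = c("dl", "sqrt_n")) {
  outcome <- match.arg(outcome)
  lnm_weighting <- match.arg(lnm_weighting)
  stopifnot(length(studies) >= 1)
  per_study <- lapply(studies, study_assoc, outcome = outcome,
                      policy = policy)
  per_study <- per_study[!vapply(per_study, is.null, TRUE)]
  if (!length(per_study))
    stop("no study is eligible for the ", outcome, " meta-analysis")
  assoc <- do.call(rbind, per_study)
  k_total <- length(per_study)
  study_n <- vapply(per_study, function(df) df$n[1], 0L)
  names(study_n) <- vapply(per_study, function(df) df$study_id[1], "")

  split_idx <- split(seq_len(nrow(assoc)), assoc$gene_id)
  genes <- names(split_idx)
  res <- data.frame(gene_id = genes,
                    meta_z = NA_real_, pooled_effect = NA_real_,
                    se = NA_real_, tau2 = NA_real_, q_stat = NA_real_,
                    n_studies = vapply(split_idx, length, 0L),
                    n_total = NA_integer_, stringsAsFactors = FALSE,
                    row.names = NULL)
  if (outcome == "lnm" && lnm_weighting == "dl") {
    for (i in seq_along(genes)) {
      rows <- assoc[split_idx[[i]], ]
      fit <- dl_random_effects(rows$effect, rows$v)
      res$meta_z[i] <- fit$meta_z
      res$pooled_effect[i] <- fit$pooled
      res$se[i] <- fit$se
      res$tau2[i] <- fit$tau2
      res$q_stat[i] <- fit$q_stat
      res$n_total[i] <- sum(rows$n)
    }
  } else {
    for (i in seq_along(genes)) {
      rows <- assoc[split_idx[[i]], ]
      res$meta_z[i] <- liptak_meta_z(rows$z, rows$n)
      res$n_total[i] <- sum(rows$n)
    }
  }
  res <- classify_genes(res, outcome = outcome, policy = policy,
                        n_total_studies = k_total)
  structure(list(results = res,
                 per_study = per_study,
                 outcome = outcome,
                 policy = policy,
                 lnm_weighting = if (outcome == "lnm") lnm_weighting
                                 else NA_character_,
                 studies = study_n,
                 call = match.call()),
            class = "hnc_meta")
}

#' @export
print.hnc_meta <- function(x, ...) {
  cat(sprintf("Gene meta-analysis: outcome = %s, %d studies (total n = %d)\n",
              x$outcome, length(x$studies), sum(x$studies)))
  tab <- table(factor(x$results$label, levels = c("pro", "anti", "ns")))
  cat(sprintf("  %d genes combined; %d pro, %d anti at |meta-z| >= %.2f\n",
              nrow(x$results), tab[["pro"]], tab[["anti"]],
              x$policy$z_threshold))
  invisible(x)
}

#' @export
summary.hnc_meta <- function(object, n_top = 5L, ...) {
  res <- object$results
  ord <- order(-abs(res$meta_z))
  structure(list(outcome = object$outcome,
                 n_studies = length(object$studies),
                 n_samples = sum(object$studies),
                 n_genes = nrow(res),
                 n_pro = sum(res$label == "pro"),
                 n_anti = sum(res$label == "anti"),
                 n_ineligible = sum(!res$eligible),
                 z_threshold = object$policy$z_threshold,
                 top = utils::head(res[ord, ], n_top)),
            class = "summary.hnc_meta")
}

#' @export
print.summary.hnc_meta <- function(x, ...) {
  cat(sprintf("Meta-analysis of gene association with %s\n", x$outcome))
  cat(sprintf("  studies: %d (n = %d); genes combined: %d (%d ineligible)\n",
              x$n_studies, x$n_samples, x$n_genes, x$n_ineligible))
  cat(sprintf("  prognostic at |meta-z| >= %.2f: %d pro, %d anti\n",
              x$z_threshold, x$n_pro, x$n_anti))
  cat("  strongest associations:\n")
  print(x$top[, c("gene_id", "meta_z", "n_studies", "label")],
        row.names = FALSE)
  invisible(x)
}

#' @export
coef.hnc_meta <- function(object, ...) {
  stats::setNames(object$results$meta_z, object$results$gene_id)
}

#' @export
as.data.frame.hnc_meta <- function(x, ...) {
  x$results
}

#' @export
plot.hnc_meta <- function(x, ...) {
  z <- x$results$meta_z
  graphics::hist(z, breaks = 50,
                 main = sprintf("Meta-z distribution (%s)", x$outcome),
                 xlab = "meta-z", col = "grey85", border = "white", ...)
  graphics::abline(v = c(-1, 1) * x$policy$z_threshold, lty = 2,
                   col = "firebrick")
  invisible(x)
}

#' Prognostic gene ids from a fitted meta-analysis
#'
#' @param fit an \code{hnc_meta} object.
#' @param direction \code{"both"}, \code{"pro"} or \code{"anti"}.
#' @return character vector of gene ids.
#' @export
prognostic_genes <- function(fit, direction = c("both", "pro", "anti")) {
  direction <- match.arg(direction)
  res <- fit$results
  keep <- if (direction == "both") res$label != "ns"
          else res$label == direction
  res$gene_id[keep]
}
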