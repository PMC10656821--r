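test_that("Liptak weighted meta-z matches hand-evaluated cases", {
  expect_equal(liptak_meta_z(2.5, 100), 2.5)
  expect_equal(liptak_meta_z(rep(2, 4), rep(50, 4)), 4)  # z * sqrt(k)
  expect_equal(liptak_meta_z(c(3, 0), c(100, 25)), 30 / sqrt(125),
               tolerance = 1e-6)
  expect_equal(liptak_meta_z(c(3, 0), c(100, 25)), 2.683282,
               tolerance = 1e-6)
  expect_error(liptak_meta_z(numeric(0), numeric(0)), "nonempty")
  expect_error(liptak_meta_z(1, 0), "positive")

  # permutation invariance in study order
  z <- c(1.2, -0.4, 2.2); n <- c(30, 100, 55)
  expect_equal(liptak_meta_z(z, n), liptak_meta_z(rev(z), rev(n)))
})

test_that("Liptak combination of null z-scores is standard normal", {
  set.seed(20)
  n_genes <- 10000
  k <- 8
  n <- sample(30:300, k)
  zmat <- matrix(rnorm(n_genes * k), n_genes, k)
  meta <- apply(zmat, 1, liptak_meta_z, n = n)
  expect_lt(abs(mean(meta)), 3 / sqrt(n_genes))
  # var of sample variance ~ 2/(n-1)
  expect_lt(abs(var(meta) - 1), 3 * sqrt(2 / (n_genes - 1)))
})

test_that("DerSimonian-Laird pooling matches hand-evaluated cases", {
  one <- dl_random_effects(0.5, 0.04)
  expect_equal(one$pooled, 0.5)
  expect_equal(one$se, 0.2)
  expect_equal(one$meta_z, 2.5, tolerance = 1e-6)
  expect_equal(one$tau2, 0)

  homo <- dl_random_effects(rep(0.3, 4), rep(0.02, 4))
  expect_equal(homo$q_stat, 0)
  expect_equal(homo$tau2, 0)
  expect_equal(homo$pooled, 0.3)

  two <- dl_random_effects(c(0.2, 0.8), c(0.05, 0.05))
  expect_equal(two$q_stat, 3.6, tolerance = 1e-9)
  expect_equal(two$tau2, 0.13, tolerance = 1e-9)
  expect_equal(two$pooled, 0.5, tolerance = 1e-9)
  expect_equal(two$se, 0.3, tolerance = 1e-9)
  expect_equal(two$meta_z, 1 / 0.6, tolerance = 1e-6)

  expect_error(dl_random_effects(c(1, 2), c(0.1, 0)), "positive")

  # permutation invariance
  d <- c(0.1, 0.5, 0.9); v <- c(0.02, 0.05, 0.08)
  expect_equal(dl_random_effects(d, v), dl_random_effects(rev(d), rev(v)))
})

test_that("DL with zero heterogeneity equals fixed-effect pooling", {
  d <- c(0.40, 0.42, 0.41, 0.40)
  v <- c(0.05, 0.04, 0.06, 0.05)
  fit <- dl_random_effects(d, v)
  expect_equal(fit$tau2, 0)
  w <- 1 / v
  expect_equal(fit$pooled, sum(w * d) / sum(w), tolerance = 1e-12)
  expect_equal(fit$se, 1 / sqrt(sum(w)), tolerance = 1e-12)
})

test_that("DL pooling matches metafor as an independent cross-check", {
  skip_if_not_installed("metafor")
  set.seed(21)
  d <- rnorm(6, 0.4, 0.3)
  v <- runif(6, 0.02, 0.1)
  mine <- dl_random_effects(d, v)
  ref <- metafor::rma(yi = d, vi = v, method = "DL")
  expect_equal(mine$pooled, unname(ref$beta[, 1]), tolerance = 1e-8)
  expect_equal(mine$se, unname(ref$se), tolerance = 1e-8)
  expect_equal(mine$tau2, unname(ref$tau2), tolerance = 1e-8)
})

test_that("classification applies inclusive thresholds and eligibility", {
  pol <- threshold_policy()
  meta <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                     meta_z = c(3.09, -3.09, 3.0899, 5, -5),
                     n_studies = c(3, 3, 3, 1, 3))
  out <- classify_genes(meta, "survival", pol)
  expect_identical(out$label, c("anti", "pro", "ns", "ns", "pro"))
  expect_false(out$eligible[4])  # one-study gene ineligible

  # LNM half-of-studies rule with opposite orientation of labels
  out2 <- classify_genes(meta, "lnm", pol, n_total_studies = 6)
  expect_identical(out2$label, c("pro", "anti", "ns", "ns", "anti"))
  expect_error(classify_genes(meta, "lnm", pol), "n_total_studies")

  # monotone: raising one z never flips pro to anti
  meta$meta_z[2] <- 10
  out3 <- classify_genes(meta, "lnm", pol, n_total_studies = 6)
  expect_identical(out3$label[2], "pro")
})

test_that("overlap and cohort summaries reproduce printed arithmetic", {
  A <- paste0("g", 1:420)
  B <- c(paste0("g", 1:324), paste0("h", 1:200))
  ov <- summarize_overlap(A, B)
  expect_equal(ov$n_overlap, 324)
  expect_equal(ov$pct_of_a, 77)
  expect_equal(summarize_overlap(A, A)$pct_of_a, 100)
  expect_error(summarize_overlap(character(0), A), "empty")

  clin <- data.frame(time_months = rep(10, 519),
                     event = rep(c(0, 1), c(299, 220)),
                     lnm_status = c(rep(c(0, 1), c(176, 244)),
                                    rep(NA, 99)))
  sm <- summarize_cohort(clin)
  expect_equal(sm$n_censored, 299)
  expect_equal(sm$n_event, 220)
  expect_equal(sm$pct_event, 42)
  expect_equal(sm$n_lnm0, 176)
  expect_equal(sm$n_lnm_pos, 244)
  expect_equal(sm$pct_lnm_pos, 58)
  expect_equal(summarize_cohort(
    data.frame(time_months = 1:5, event = rep(0, 5)))$pct_event, 0)
})

test_that("half-up rounding governs printed percentages", {
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(2.5), 3)   # round() would give 2
  expect_equal(round_half_up(-2.5), -3)
  expect_equal(pct(1, 8), 13)           # 12.5 rounds up
  expect_equal(pct(742, 877), 85)
  expect_equal(pct(958, 1212), 79)
})

test_that("hnc_meta recovers planted LNM effects with correct labels", {
  fit <- suppressMessages(hnc_meta(fixture_studies(), "lnm"))
  expect_s3_class(fit, "hnc_meta")
  res <- fit$results
  truth <- fixture_compendium()$truth
  eff <- truth$true_lnm_effect[match(res$gene_id, truth$gene_id)]
  expect_true(all(res$label[eff > 0] == "pro"))
  expect_true(all(res$label[eff < 0] == "anti"))
  expect_lt(mean(res$label[eff == 0] != "ns"), 0.02)
  # pooled effects near the planted d
  expect_lt(abs(mean(res$pooled_effect[eff > 0]) - 0.8), 0.15)
  expect_true(all(res$tau2 >= 0))
  expect_true(all(abs(res$meta_z - res$pooled_effect / res$se) < 1e-6 |
                    is.na(res$se)))
})

test_that("hnc_meta S3 surface behaves like a model object", {
  fit <- suppressMessages(hnc_meta(fixture_studies(), "grade"))
  expect_output(print(fit), "outcome = grade")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.hnc_meta")
  expect_output(print(sm), "strongest associations")
  cf <- coef(fit)
  expect_named(cf)
  expect_identical(names(cf), fit$results$gene_id)
  expect_identical(as.data.frame(fit), fit$results)
  expect_setequal(prognostic_genes(fit),
                  c(prognostic_genes(fit, "pro"),
                    prognostic_genes(fit, "anti")))
  path <- tempfile(fileext = ".png")
  grDevices::png(path)
  plot(fit)
  grDevices::dev.off()
  expect_true(file.exists(path))
  unlink(path)
})

test_that("sqrt-n weighting variant is available for LNM sensitivity analysis", {
  fit_dl <- suppressMessages(hnc_meta(fixture_studies(), "lnm"))
  fit_sn <- suppressMessages(hnc_meta(fixture_studies(), "lnm",
                                      lnm_weighting = "sqrt_n"))
  # same strongly-planted genes significant under both weightings
  truth <- fixture_compendium()$truth
  planted <- truth$gene_id[truth$true_lnm_effect != 0]
  res_sn <- fit_sn$results
  expect_true(all(res_sn$label[res_sn$gene_id %in% planted] != "ns"))
  expect_false(identical(fit_dl$results$meta_z, fit_sn$results$meta_z))
})
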