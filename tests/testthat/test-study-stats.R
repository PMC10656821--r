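test_that("cox_z validates input and matches coxph on clean data", {
  set.seed(1)
  n <- 60
  x <- rnorm(n)
  s <- simulate_survival(0.5 * x, 0.05, 0.3)
  a <- cox_z(x, s$time_months, s$event)
  fit <- survival::coxph(survival::Surv(s$time_months, s$event) ~ x,
                         ties = "efron")
  expect_equal(a$effect, unname(coef(fit)), tolerance = 1e-8)
  expect_equal(a$z, unname(coef(fit)) / sqrt(vcov(fit)[1, 1]),
               tolerance = 1e-8)
  expect_equal(a$z, a$effect / a$se, tolerance = 1e-6)

  expect_error(cox_z(rep(1, n), s$time_months, s$event), "zero-variance")
  expect_error(cox_z(x[1:10], s$time_months[1:10], s$event[1:10]),
               "fewer than 20")
  expect_error(cox_z(x, s$time_months, rep(0, n)), "fewer than 2 events")
})

test_that("cox z-scores are calibrated under the null and recover effects", {
  # null calibration: rejection at |z| > 1.96 close to 0.05
  set.seed(2)
  n_rep <- 400
  rej <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    x <- rnorm(100)
    s <- simulate_survival(rep(0, 100), 0.05, 0.3)
    rej[r] <- abs(cox_z(x, s$time_months, s$event)$z) > 1.96
  }
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(mean(rej) - 0.05), 3 * se)

  # sign convention: positive log-hazard gives positive mean z
  set.seed(3)
  zs <- replicate(50, {
    x <- rnorm(150)
    s <- simulate_survival(0.5 * x, 0.05, 0.3)
    cox_z(x, s$time_months, s$event)$z
  })
  expect_gt(mean(zs), 0)
})

test_that("smd_lnm reproduces the hand-computed example and its variance", {
  a <- smd_lnm(c(2, 4, 1, 3), c(1, 1, 0, 0), group_floor = 2)
  expect_equal(a$effect, 1 / sqrt(2), tolerance = 1e-9)
  expect_equal(a$v, 1.0625, tolerance = 1e-9)
  expect_equal(a$z, a$effect / sqrt(a$v), tolerance = 1e-9)
  expect_equal(a$n1 + a$n0, a$n)

  same <- smd_lnm(c(1, 2, 3, 1, 2, 3), c(1, 1, 1, 0, 0, 0),
                  group_floor = 3)
  expect_equal(same$effect, 0)

  # antisymmetry under label swap
  set.seed(4)
  x <- rnorm(40); g <- rep(0:1, 20)
  d1 <- smd_lnm(x, g)
  d2 <- smd_lnm(x, 1 - g)
  expect_equal(d1$effect, -d2$effect)
  expect_equal(d1$v, d2$v)

  expect_error(smd_lnm(x, c(rep(1, 4), rep(0, 36))), "fewer than 5")
  expect_error(smd_lnm(rep(1, 20), rep(0:1, 10)), "constant")
})

test_that("smd_lnm recovers a planted unit difference at large n", {
  set.seed(5)
  x <- c(rnorm(4000, 1), rnorm(4000, 0))
  g <- rep(c(1, 0), each = 4000)
  expect_lt(abs(smd_lnm(x, g)$effect - 1), 0.05)
  # Hedges correction shrinks d slightly
  expect_lt(abs(smd_lnm(x, g, hedges = TRUE)$effect),
            abs(smd_lnm(x, g)$effect))
})

test_that("grade_z matches lm and is calibrated under permutation", {
  set.seed(6)
  grade <- sample(1:4, 50, replace = TRUE)
  expr <- 0.5 * grade + rnorm(50)
  a <- grade_z(expr, grade)
  fit <- summary(lm(expr ~ grade))
  expect_equal(a$effect, unname(fit$coefficients["grade", "Estimate"]),
               tolerance = 1e-9)
  expect_equal(a$z, unname(fit$coefficients["grade", "t value"]),
               tolerance = 1e-9)
  expect_gt(a$z, 0)

  expect_error(grade_z(rep(1, 20), sample(1:4, 20, TRUE)),
               "zero-variance")
  expect_error(grade_z(rnorm(20), rep(2, 20)), "single grade")

  # permutation null calibration of the t-test at level 0.05
  set.seed(7)
  n_rep <- 1000
  crit <- qt(0.975, 50 - 2)
  rej <- replicate(n_rep, {
    abs(grade_z(rnorm(50), sample(grade))$z) > crit
  })
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("signature scores are means over present genes", {
  m <- mk_matrix(rbind(c(1, 4), c(2, 5), c(3, 6)),
                 genes = c("a", "b", "c"))
  one <- signature_score(m, "b")
  expect_equal(one$score, unname(m["b", ]))
  sc <- signature_score(m, c("a", "b", "c"))
  expect_equal(sc$score, c(2, 5))
  expect_warning(part <- signature_score(m, c("a", "b", "x", "y")),
                 "2/4")
  expect_equal(part$score, unname(colMeans(m[c("a", "b"), ])))
  expect_equal(part$n_genes_used[1], 2)
  expect_equal(part$n_genes_in_signature[1], 4)
  expect_error(signature_score(m, c("x", "y")), "no signature genes")

  # union property: score of a disjoint union is the size-weighted mean
  s1 <- signature_score(m, c("a", "b"))$score
  s2 <- signature_score(m, "c")$score
  su <- signature_score(m, c("a", "b", "c"))$score
  expect_equal(su, (2 * s1 + 1 * s2) / 3)
})

test_that("signature scoring is invariant to per-study affine rescaling", {
  # standardization absorbs any per-study affine change of scale, so the
  # downstream signature scores are unchanged
  set.seed(13)
  m <- mk_matrix(matrix(rnorm(200, 8, 2), 20, 10),
                 genes = sprintf("G%05d", 1:20))
  m_resc <- 2.5 * m + 7
  sig <- sprintf("G%05d", c(2, 5, 9, 14))
  expect_equal(signature_score(standardize_genes(m), sig)$score,
               signature_score(standardize_genes(m_resc), sig)$score,
               tolerance = 1e-12)
})

test_that("EMT score is mesenchymal sum minus epithelial sum", {
  genes <- c("VIM", "CDH2", "FOXC2", "SNAI1", "SNAI2", "TWIST1", "GSC",
             "FN1", "ITGB6", "MMP2", "MMP3", "MMP9", "SOX10",
             "CDH1", "DSP", "TJP1")
  m <- mk_matrix(matrix(0, 16, 2), genes = genes)
  expect_equal(unname(emt_score(m)), c(0, 0))

  m2 <- m
  m2[1:13, ] <- 1  # each mesenchymal gene = 1
  expect_equal(unname(emt_score(m2)), c(13, 13))

  m3 <- m
  m3["CDH1", ] <- 5; m3["DSP", ] <- 3; m3["TJP1", ] <- 2
  expect_equal(unname(emt_score(m3)), c(-10, -10))

  expect_warning(partial <- emt_score(m[1:5, , drop = FALSE]),
                 "absent")
  expect_length(partial, 2)
})

test_that("adjusted association enforces the 10-case floor and tracks confounding", {
  set.seed(8)
  n <- 300
  clin <- data.frame(sample_id = as.character(1:n),
                     hpv_status = rbinom(n, 1, 0.3))
  score <- rnorm(n)
  s <- simulate_survival(0.7 * score, 0.03, 0.3)
  clin$time_months <- s$time_months
  clin$event <- s$event
  adj <- adjusted_assoc(score, clin, "survival")
  expect_gt(adj$z, 2)

  small <- clin[1:9, ]
  expect_message(res <- adjusted_assoc(score[1:9], small, "survival"),
                 "excluded")
  expect_null(res)

  # confounding: HPV shifts both the score and LNM odds, so adjusting
  # must shrink the association of a score that only tracks HPV
  set.seed(9)
  shrink <- replicate(30, {
    hpv <- rbinom(n, 1, 0.4)
    score2 <- 1.5 * hpv + rnorm(n)
    lnm <- rbinom(n, 1, plogis(-0.5 + 2 * hpv))
    cl <- data.frame(sample_id = as.character(1:n), hpv_status = hpv,
                     lnm_status = lnm)
    za <- adjusted_assoc(score2, cl, "lnm")$z
    zu <- adjusted_assoc(score2, cl, "lnm",
                         covariates = character(0))$z
    abs(za) < abs(zu)
  })
  expect_gt(mean(shrink), 0.8)
})

test_that("unadjusted and adjusted z agree when the covariate is irrelevant", {
  set.seed(10)
  diffs <- replicate(60, {
    n <- 400
    hpv <- rbinom(n, 1, 0.3)
    score <- rnorm(n)
    lnm <- rbinom(n, 1, plogis(0.5 * score))
    cl <- data.frame(sample_id = as.character(1:n), hpv_status = hpv,
                     lnm_status = lnm)
    adjusted_assoc(score, cl, "lnm")$z -
      adjusted_assoc(score, cl, "lnm", covariates = character(0))$z
  })
  expect_lt(mean(abs(diffs)), 0.2)
})

test_that("group comparison gives the exact Wilcoxon p on the toy example", {
  res <- compare_groups(c(1, 2, 3, 4, 5, 6), c(0, 0, 0, 1, 1, 1))
  expect_true(res$exact)
  expect_equal(res$wilcoxon_p, 0.1, tolerance = 1e-12)
  expect_error(compare_groups(1:5, rep(1, 5)), "2 nonempty levels")

  # with a covariate the adjusted coefficient is reported
  set.seed(11)
  g <- rep(0:1, each = 30)
  x <- 0.5 * g + rnorm(60)
  res2 <- compare_groups(x, g, covariates = data.frame(c1 = rnorm(60)))
  expect_true(is.finite(res2$adjusted_coef))
  expect_true(res2$adjusted_p <= 1)
})

test_that("Wilcoxon p-values are uniform under the null", {
  set.seed(12)
  ps <- replicate(1000, compare_groups(rnorm(40), rep(0:1, 20))$wilcoxon_p)
  # p-values of a rank test are discrete, so silence the KS ties warning
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("study_assoc agrees with the single-gene operations", {
  st <- fixture_studies()[[1]]
  pol <- threshold_policy()

  lnm_tab <- study_assoc(st, "lnm", pol)
  g <- lnm_tab$gene_id[7]
  single <- smd_lnm(st$expression[g, ], st$clinical$lnm_status,
                    gene_id = g)
  row <- lnm_tab[lnm_tab$gene_id == g, ]
  expect_equal(row$effect, single$effect, tolerance = 1e-10)
  expect_equal(row$v, single$v, tolerance = 1e-10)

  grade_tab <- study_assoc(st, "grade", pol)
  g2 <- grade_tab$gene_id[3]
  single2 <- grade_z(st$expression[g2, ], st$clinical$grade)
  row2 <- grade_tab[grade_tab$gene_id == g2, ]
  expect_equal(row2$z, single2$z, tolerance = 1e-8)

  surv_tab <- study_assoc(st, "survival", pol)
  g3 <- surv_tab$gene_id[5]
  single3 <- cox_z(st$expression[g3, ], st$clinical$time_months,
                   st$clinical$event)
  row3 <- surv_tab[surv_tab$gene_id == g3, ]
  expect_equal(row3$z, single3$z, tolerance = 1e-8)
})
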