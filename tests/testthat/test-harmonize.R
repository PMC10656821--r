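test_that("missingness filter drops samples first, then genes", {
  m <- mk_matrix(matrix(1:50, 10, 5))
  expect_identical(filter_missingness(m), m)  # no missing values

  m2 <- m
  m2[1:2, 1] <- NA  # sample s1 missing 20% of genes
  expect_identical(colnames(filter_missingness(m2)),
                   c("s2", "s3", "s4", "s5"))

  # two-pass rule on a 3x3 toy: s1 misses 2/3 genes -> dropped first;
  # then g1 misses 1/2 of the remaining samples -> dropped second
  m3 <- mk_matrix(matrix(1, 3, 3))
  m3[1:2, 1] <- NA
  m3[1, 2] <- NA
  out <- filter_missingness(m3, 1 / 2, 1 / 2)
  expect_identical(colnames(out), c("s2", "s3"))
  expect_identical(rownames(out), c("g2", "g3"))

  m4 <- mk_matrix(matrix(NA_real_, 2, 2))
  expect_error(filter_missingness(m4), "no usable data")
})

test_that("quantile normalization maps columns onto the mean distribution", {
  m <- mk_matrix(cbind(c(1, 2, 3), c(4, 5, 6)))
  out <- quantile_normalize(m)
  expect_equal(unname(out[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, 2]), c(2.5, 3.5, 4.5))

  same <- mk_matrix(cbind(c(2, 9, 4), c(2, 9, 4)))
  expect_equal(quantile_normalize(same), same)

  # defining property: identical value multisets per column; idempotence
  set.seed(1)
  r <- mk_matrix(matrix(rexp(60), 10, 6))
  qn <- quantile_normalize(r)
  for (j in 2:6)
    expect_equal(sort(qn[, j]), sort(qn[, 1]), ignore_attr = TRUE)
  expect_equal(quantile_normalize(qn), qn, tolerance = 1e-10)

  # order within each column is preserved
  expect_equal(apply(qn, 2, rank), apply(r, 2, rank))
  expect_error(quantile_normalize(mk_matrix(cbind(c(1, NA)))), "complete")
})

test_that("quantile normalization agrees with limma on tie-free data", {
  skip_if_not_installed("limma")
  set.seed(2)
  r <- mk_matrix(matrix(rnorm(200), 20, 10))
  expect_equal(unname(quantile_normalize(r)),
               unname(limma::normalizeQuantiles(r)), tolerance = 1e-12)
})

test_that("ties receive the mean of the reference values over their span", {
  m <- mk_matrix(cbind(c(1, 1, 5), c(2, 4, 6)))
  out <- quantile_normalize(m)
  ref <- unname(rowMeans(apply(m, 2, sort)))  # 1.5, 2.5, 5.5
  expect_equal(unname(out[, 1]), c(mean(ref[1:2]), mean(ref[1:2]), ref[3]))
})

test_that("maxmean collapse keeps the highest-mean probe per gene", {
  pm <- mk_matrix(rbind(c(1, 3), c(4, 6), c(2, 2)),
                  genes = c("p1", "p2", "p3"))
  map <- c(p1 = "gA", p2 = "gA", p3 = "gB")
  out <- collapse_probes_maxmean(pm, map)
  expect_equal(unname(out["gA", ]), c(4, 6))  # mean 5 beats mean 2
  expect_equal(unname(out["gB", ]), c(2, 2))  # single probe retained
  expect_identical(colnames(out), colnames(pm))
  expect_identical(unname(attr(out, "selected_probe")["gA"]), "p2")

  # exact tie in means: lexicographically smallest probe id wins
  tie <- mk_matrix(rbind(c(1, 3), c(3, 1)), genes = c("pB", "pA"))
  mapt <- c(pA = "g", pB = "g")
  outt <- collapse_probes_maxmean(tie, mapt)
  expect_identical(unname(attr(outt, "selected_probe")["g"]), "pA")
  expect_equal(nrow(outt), 1L)

  expect_error(collapse_probes_maxmean(pm, map[1:2]), "cover")
})

test_that("log2 transform applies offset on linear scale only", {
  m <- mk_matrix(cbind(c(0, 3), c(1, 7)))
  out <- log2_transform(m)
  expect_equal(unname(out), cbind(c(0, 2), c(1, 3)))
  expect_identical(log2_transform(m, already_log = TRUE), m)
  neg <- mk_matrix(cbind(c(-1, 1)))
  expect_error(log2_transform(neg), "negative")
  expect_false(guess_log_scale(mk_matrix(cbind(c(10, 6000)))))
  expect_true(guess_log_scale(mk_matrix(cbind(c(2, 14)))))
})

test_that("standardization yields mean-0, sample-SD-1 rows", {
  m <- mk_matrix(rbind(c(1, 2, 3), c(10, 20, 60)))
  out <- standardize_genes(m)
  expect_equal(unname(out[1, ]), c(-1, 0, 1))  # sample SD is exactly 1
  expect_equal(unname(rowMeans(out)), c(0, 0), tolerance = 1e-8)
  expect_equal(unname(apply(out, 1, sd)), c(1, 1), tolerance = 1e-8)

  const <- mk_matrix(rbind(c(1, 2, 3), c(5, 5, 5)))
  expect_warning(out2 <- standardize_genes(const), "zero-variance")
  expect_identical(rownames(out2), "g1")

  # missing entries stay missing and are excluded from mean/SD
  mm <- mk_matrix(rbind(c(1, 2, 3, NA)))
  sm <- standardize_genes(mm)
  expect_true(is.na(sm[1, 4]))
  expect_equal(mean(sm[1, 1:3]), 0, tolerance = 1e-8)
})

test_that("sex concordance QC compares XIST-RPS4Y1 with annotation", {
  m <- mk_matrix(rbind(XIST = c(8, 2, 9, 3), RPS4Y1 = c(2, 8, 1, 9)),
                 genes = c("XIST", "RPS4Y1"))
  clin <- data.frame(sample_id = colnames(m),
                     sex = c("female", "female", "male", "male"))
  qc <- check_sex_concordance(m, clin)
  expect_identical(unname(qc$inferred_sex),
                   c("female", "male", "female", "male"))
  # s2 (annotated female, inferred male) and s3 discordant
  expect_equal(qc$discordance_fraction, 0.5)

  clin$sex[2] <- "male"
  clin$sex[3] <- "female"
  expect_equal(check_sex_concordance(m, clin)$discordance_fraction, 0)

  clin2 <- data.frame(sample_id = colnames(m),
                      sex = c("female", "male", "female", "female"))
  expect_equal(check_sex_concordance(m, clin2)$discordance_fraction, 0.25)
  expect_warning(res <- check_sex_concordance(
    mk_matrix(rbind(c(1, 2))), clin), "skipped")
  expect_null(res)
})

test_that("complete-matrix assembly enforces the 80% rule", {
  genes <- sprintf("G%02d", 1:20)
  mk_study <- function(id, gene_subset, n) {
    set.seed(nchar(id) + n)
    structure(list(expression = mk_matrix(
      matrix(rnorm(length(gene_subset) * n), length(gene_subset), n),
      genes = gene_subset,
      samples = sprintf("%s_s%d", id, 1:n)),
      clinical = NULL, study_id = id, n_samples = n),
      class = "study_dataset")
  }
  s_full <- mk_study("full", genes, 5)        # 100% coverage
  s_85 <- mk_study("mid", genes[1:17], 4)     # 85%
  s_50 <- mk_study("low", genes[1:10], 3)     # 50% -> excluded entirely
  out <- assemble_complete_matrix(list(s_full, s_85, s_50), genes)
  expect_equal(ncol(out), 9)                   # 5 + 4 + 0 samples
  expect_identical(rownames(out), genes[1:17]) # complete genes only
  expect_equal(attr(out, "retention_pct"), 85) # 17/20
  expect_equal(unname(attr(out, "samples_per_study")["low"]), 0L)

  # all studies measure all genes: full concatenation, all genes kept
  out2 <- assemble_complete_matrix(list(s_full, mk_study("b", genes, 3)),
                                   genes)
  expect_equal(dim(out2), c(20L, 8L))

  expect_error(assemble_complete_matrix(list(s_50), genes),
               "coverage rule")
})

test_that("harmonized studies expose standardized expression aligned to clinical", {
  st <- fixture_studies()[[1]]
  expect_s3_class(st, "study_dataset")
  expect_identical(colnames(st$expression), st$clinical$sample_id)
  sds <- apply(st$expression, 1, sd)
  expect_true(all(abs(sds - 1) < 1e-8))
  # simulated sex markers make the QC clean
  expect_lt(st$sex_qc$discordance_fraction, 0.05)
})
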