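# Two-group tests, FDR control and symptom regression.

test_that("pooled t-test matches hand computation and is antisymmetric", {
  r <- two_sample_ttest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, (2 - 5) / sqrt(2 / 3), tolerance = 1e-12)  # pooled sd 1
  expect_equal(r$t, -3.674, tolerance = 1e-3)
  expect_equal(r$p, 0.0213, tolerance = 1e-3)
  expect_equal(r$p, 2 * pt(-abs(r$t), df = 4), tolerance = 1e-12)
  rs <- two_sample_ttest(c(4, 5, 6), c(1, 2, 3))
  expect_equal(rs$t, -r$t)
  expect_equal(rs$p, r$p)
  same <- two_sample_ttest(c(1, 2, 3), c(3, 2, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(two_sample_ttest(rep(1, 3), rep(1, 4)), "degenerate")
})

test_that("pooled t-test p approximates a permutation oracle", {
  set.seed(1)
  x0 <- rnorm(8); x1 <- rnorm(8, mean = 1)
  t_obs <- two_sample_ttest(x0, x1)$t
  pool <- c(x0, x1)
  perm <- replicate(4000, {
    i <- sample(16, 8)
    two_sample_ttest(pool[i], pool[-i])$t
  })
  p_perm <- mean(abs(perm) >= abs(t_obs))
  expect_lt(abs(two_sample_ttest(x0, x1)$p - p_perm), 0.05)
})

test_that("BH-FDR equals the brute-force step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.5), 0.05),
               c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(bh_fdr(rep(1, 6), 0.05), rep(FALSE, 6))
  set.seed(2)
  for (i in 1:30) {
    m <- sample(1:8, 1)
    p <- round(runif(m), 3)
    expect_equal(bh_fdr(p, 0.05), bh_oracle(p, 0.05))
    expect_equal(bh_fdr(p, 0.2), bh_oracle(p, 0.2))
  }
  # rejections are monotone non-increasing in each p-value
  p <- c(0.01, 0.04, 0.2)
  base <- sum(bh_fdr(p, 0.05))
  expect_lte(sum(bh_fdr(c(0.03, 0.04, 0.2), 0.05)), base + 1)
})

test_that("family tests flag planted effects and respect family structure", {
  co <- generate_cohort(n_group0 = 40, n_group1 = 40,
                        effect_spec = list(occupancy = 1.5),
                        T_win = 50, target_state = 2, seed = 3)
  ft <- feature_table(co$memberships, covariates = co$covariates)
  res <- run_family_tests(ft)
  expect_true(all(res$significant_fdr <= res$significant_uncorrected))
  row <- res[res$feature == "ocr_state2", ]
  expect_true(row$significant_fdr)
  expect_lt(row$t, 0)  # patient group higher => negative t (group0 - group1)
  # single-feature family: FDR flag equals the uncorrected flag
  fam1 <- attr(ft, "families")
  fam1[] <- "bulk"; fam1["nst"] <- "solo"
  res1 <- run_family_tests(ft, family_map = fam1)
  solo <- res1[res1$family == "solo", ]
  expect_equal(solo$significant_fdr, solo$significant_uncorrected)
})

test_that("symptom regression recovers a planted linear coefficient", {
  set.seed(4)
  n <- 150
  cov <- data.frame(subject_id = sprintf("s%03d", 1:n), group = 1L,
                    age = rnorm(n, 40, 10), gender = rbinom(n, 1, 0.5),
                    site = factor(sample(1:7, n, TRUE)),
                    panss_neg = rnorm(n, 15, 5))
  tbl <- data.frame(subject_id = cov$subject_id,
                    f1 = 2 * cov$panss_neg + rnorm(n, 0, 0.1),
                    f2 = rnorm(n))
  tbl <- merge(tbl, cov, by = "subject_id")
  attr(tbl, "families") <- c(f1 = "average", f2 = "average")
  res <- symptom_regression(tbl)
  expect_gt(res$coefficient[res$feature == "f1"], 1.9)
  expect_lt(res$coefficient[res$feature == "f1"], 2.1)
  expect_true(res$significant_fdr[res$feature == "f1"])

  # affine shift of a covariate leaves the symptom slope unchanged
  tbl2 <- tbl; tbl2$age <- tbl2$age + 100
  attr(tbl2, "families") <- attr(tbl, "families")
  res2 <- symptom_regression(tbl2)
  expect_equal(res2$coefficient, res$coefficient, tolerance = 1e-8)

  # collinear design is refused
  tbl3 <- tbl; tbl3$gender <- 1L
  attr(tbl3, "families") <- attr(tbl, "families")
  expect_error(symptom_regression(tbl3), "collinearity")
})
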