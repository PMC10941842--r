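# Dynamical and stability features from membership series.

test_that("hard assignment takes the argmax with low-index ties", {
  expect_equal(hard_assign(rbind(c(0.9, 0.1), c(0.2, 0.8))), c(1, 2))
  expect_equal(hard_assign(rbind(c(0.5, 0.5))), 1)
  U <- diag(3)[c(2, 3, 1), ]
  expect_equal(hard_assign(U), c(2, 3, 1))
})

test_that("occupancy rates count states as percentages summing to 100", {
  expect_equal(ocr(c(1, 1, 2, 2), 2), c(50, 50))
  expect_equal(ocr(c(3, 3, 3), 3), c(0, 0, 100))
  set.seed(1)
  s <- sample(1:4, 57, replace = TRUE)
  expect_equal(sum(ocr(s, 4)), 100)
  expect_error(ocr(integer(0), 3), "empty")
})

test_that("transition counts match their definition and bounds", {
  expect_equal(nst(c(1, 1, 1)), 0)
  expect_equal(nst(c(1, 2, 1, 2)), 3)
  set.seed(2)
  s <- sample(1:3, 40, replace = TRUE)
  expect_gte(nst(s), 0)
  expect_lte(nst(s), 39)
})

test_that("probability statistics give 3 features per state", {
  U <- generate_membership_trajectories(50, 5, seed = 3)
  ps <- prob_stats(U)
  expect_length(ps, 15)
  expect_equal(sum(ps[paste0("mean_state", 1:5)]), 1)
  Uc <- cbind(rep(0.3, 10), rep(0.7, 10))
  psc <- prob_stats(Uc)
  expect_equal(unname(psc), c(0.3, 0.7, 0, 0, 0, 0))
})

test_that("cumulative difference sums absolute consecutive changes", {
  U <- generate_membership_trajectories(40, 5, seed = 4)
  cd <- cumulative_difference(U)
  expect_length(cd, 5)
  expect_true(all(cd >= 0))
  expect_equal(unname(cumulative_difference(matrix(0.5, 6, 2))), c(0, 0))
  expect_equal(unname(cumulative_difference(cbind(c(0, 1, 0), c(1, 0, 1)))),
               c(2, 2))
  expect_error(cumulative_difference(matrix(1, 1, 2)), "too short")

  # one-hot series: per-state cumulative change is twice the number of run
  # boundaries involving the state (entries + exits), by a boundary-count
  # oracle
  set.seed(5)
  s <- sample(1:3, 30, replace = TRUE)
  U1 <- diag(3)[s, ]
  cd1 <- cumulative_difference(U1)
  oracle <- vapply(1:3, function(k) {
    inK <- s == k
    sum(abs(diff(inK)))
  }, numeric(1))
  expect_equal(unname(cd1), oracle)
})

test_that("entropy over time attains its uniform maximum and bounds", {
  U <- matrix(0.25, 20, 4)
  expect_equal(unname(entropy_over_time(U)), rep(log(20), 4))
  spike <- cbind(c(1 - 1e-9 * 18, rep(1e-10, 18), 1e-10))
  expect_lt(entropy_over_time(spike)[1], 0.01)
  Ur <- generate_membership_trajectories(64, 3, seed = 6)
  H <- entropy_over_time(Ur)
  expect_true(all(H >= 0 & H <= log(64)))
})

test_that("consecutive KLD statistics summarize step divergences", {
  expect_equal(unname(consecutive_kld_stats(matrix(0.5, 8, 2))),
               c(0, 0, 0, 0, 0))
  U <- matrix(0.5, 8, 2)
  U[5, ] <- c(0.9, 0.1)   # two nonzero steps among seven
  st <- consecutive_kld_stats(U)
  expect_gt(st["kld_max"], 0)
  expect_equal(unname(st["kld_median"]), 0)
  expect_lte(st["kld_min"], st["kld_median"])
  expect_lte(st["kld_median"], st["kld_max"])
  expect_error(consecutive_kld_stats(matrix(1, 1, 2)), "too short")
})

test_that("nonuniformity measures deviation from the 1/K level", {
  expect_equal(unname(nonuniformity(matrix(0.25, 10, 4))), rep(0, 4))
  U <- cbind(rep(1, 6), rep(0, 6))
  expect_equal(unname(nonuniformity(U)), c(0.25, 0.25))
  Ur <- generate_membership_trajectories(30, 5, seed = 7)
  nu <- nonuniformity(Ur)
  expect_true(all(nu >= 0 & nu <= max((1 - 1 / 5)^2, (1 / 5)^2)))
})

test_that("state correlations follow complementarity and pair counts", {
  U2 <- generate_membership_trajectories(50, 2, seed = 8)
  expect_equal(unname(state_correlations(U2)), -1)
  U5 <- generate_membership_trajectories(50, 5, seed = 9)
  sc <- state_correlations(U5)
  expect_length(sc, 10)
  expect_true(all(sc >= -1 & sc <= 1))
  Uc <- cbind(rep(0.5, 10), runif(10) / 4, 0.5 - runif(10) / 4)
  Uc[, 3] <- 1 - Uc[, 1] - Uc[, 2]
  expect_warning(scc <- state_correlations(cbind(Uc[, 1], Uc[, 2], Uc[, 3])),
                 "constant")
  expect_equal(unname(scc[1:2]), c(0, 0))
})

test_that("LP2D subject features average windows within subject", {
  lp <- rbind(matrix(2, 3, 2), matrix(4, 3, 2))
  colnames(lp) <- c("IC2/IC1", "IC3/IC1")
  subj <- rep(c("a", "b"), each = 3)
  sf <- lp2d_subject_features(lp, subj)
  expect_equal(unname(sf), rbind(c(2, 2), c(4, 4)))
  expect_equal(colnames(sf), c("lp2d_IC2_IC1", "lp2d_IC3_IC1"))
  # grand mean with equal window counts partitions the pooled mean
  expect_equal(mean(sf), mean(lp))
  expect_equal(unname(lp2d_subject_features(lp * 0, subj)),
               matrix(0, 2, 2))
  expect_error(lp2d_subject_features(lp, subj[-1]), "exactly one subject")
})

test_that("the feature table assembles all families with conserved OCR", {
  co <- generate_cohort(n_group0 = 4, n_group1 = 4, T_win = 30,
                        n_sites = 2, seed = 10)
  ft <- feature_table(co$memberships, covariates = co$covariates)
  fam <- attr(ft, "families")
  expect_setequal(unique(unname(fam)),
                  c("nst_ocr", "nonuniformity_kld_entropy", "average",
                    "variance", "range", "correlation",
                    "cumulative_difference"))
  ocr_cols <- paste0("ocr_state", 1:5)
  expect_equal(unname(rowSums(ft[, ocr_cols])), rep(100, 8))
  expect_false(anyNA(ft[, names(fam)]))
  # deterministic extraction
  ft2 <- feature_table(co$memberships, covariates = co$covariates)
  expect_identical(ft, ft2)
})
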