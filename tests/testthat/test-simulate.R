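# Synthetic-data generators: planted centroids, trajectories, dFNC, cohorts.

test_that("generate_centroids respects separation and seeding", {
  c1 <- generate_centroids(1, C = 7, separation = 1, seed = 0)
  expect_equal(dim(c1), c(1, 21))
  expect_true(all(abs(c1) <= 1))

  c2 <- generate_centroids(2, C = 3, separation = 2, seed = 0)
  expect_gte(sqrt(sum((c2[1, ] - c2[2, ])^2)), 2)

  a <- generate_centroids(5, C = 7, separation = 1.5, seed = 0)
  b <- generate_centroids(5, C = 7, separation = 1.5, seed = 1)
  expect_false(identical(a, b))
  expect_identical(a, generate_centroids(5, C = 7, separation = 1.5, seed = 0))
  expect_gte(min(dist(a)), 1.5)

  # too many patterns at an impossible separation in a bounded cube
  expect_error(generate_centroids(50, C = 3, separation = 3.4, seed = 0,
                                  max_tries = 50),
               "infeasible separation")
})

test_that("membership trajectories are row-stochastic and smoothness-responsive", {
  U1 <- generate_membership_trajectories(10, 1, seed = 0)
  expect_equal(unname(U1), matrix(1, 10, 1))

  U <- generate_membership_trajectories(200, 4, seed = 1)
  expect_equal(rowSums(U), rep(1, 200), tolerance = 1e-9)
  expect_true(all(U >= 0 & U <= 1))

  s0 <- generate_membership_trajectories(100, 3, smoothness = 0, seed = 2)
  s20 <- generate_membership_trajectories(100, 3, smoothness = 20, seed = 2)
  expect_lt(mean(abs(diff(s20))), mean(abs(diff(s0))))

  # concentration pushes rows toward one-hot
  lo <- generate_membership_trajectories(100, 3, concentration = 0.1, seed = 3)
  hi <- generate_membership_trajectories(100, 3, concentration = 3, seed = 3)
  expect_gt(mean(apply(hi, 1, max)), mean(apply(lo, 1, max)))

  expect_error(generate_membership_trajectories(10, 0), "empty state space")
})

test_that("generate_dfnc mixes centroids convexly with additive noise", {
  cent <- rbind(a = c(0.5, -0.5, 0.2), b = c(-0.4, 0.3, -0.1))
  U <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5))
  d <- generate_dfnc(U, cent, noise_sd = 0, seed = 0)
  expect_equal(unname(d$values[1, ]), unname(cent[1, ]))
  expect_equal(unname(d$values[2, ]), unname(cent[2, ]))
  expect_equal(unname(d$values[3, ]), unname(colMeans(cent)))

  # with noise, the window mean under fixed u approaches the mixture
  U2 <- matrix(rep(c(0.3, 0.7), each = 200), 200, 2)
  d2 <- generate_dfnc(U2, cent, noise_sd = 0.1, seed = 1)
  mix <- as.numeric(c(0.3, 0.7) %*% cent)
  se <- 0.1 / sqrt(200)
  expect_true(all(abs(colMeans(d2$values) - mix) < 3 * se))
})

test_that("component time series reject invalid covariances and obey regimes", {
  S <- diag(2)
  expect_error(generate_component_timeseries(
    list(list(cov = matrix(c(1, 2, 2, 1), 2), duration = 10))),
    "positive semi-definite")
  ts <- generate_component_timeseries(list(list(cov = S, duration = 2000)),
                                      seed = 1)
  expect_equal(dim(ts), c(2000, 2))
  expect_lt(abs(cor(ts)[1, 2]), 0.1)
})

test_that("cohorts carry groups, covariates and reproducible structure", {
  co <- generate_cohort(n_group0 = 8, n_group1 = 6, effect_spec = list(),
                        T_win = 30, n_sites = 3, seed = 11)
  expect_length(co$dfnc, 14)
  expect_equal(sum(co$covariates$group == 0), 8)
  expect_equal(sum(co$covariates$group == 1), 6)
  expect_true(all(is.na(co$covariates$panss_neg[co$covariates$group == 0])))
  expect_true(all(!is.na(co$covariates$panss_neg[co$covariates$group == 1])))
  expect_equal(nlevels(co$covariates$site), 3)
  co2 <- generate_cohort(n_group0 = 8, n_group1 = 6, effect_spec = list(),
                         T_win = 30, n_sites = 3, seed = 11)
  expect_identical(co$dfnc[[1]]$values, co2$dfnc[[1]]$values)
  expect_identical(co$covariates, co2$covariates)
})

test_that("a planted occupancy effect shifts the target state's occupancy", {
  co <- generate_cohort(n_group0 = 50, n_group1 = 50,
                        effect_spec = list(occupancy = 1.5),
                        T_win = 60, target_state = 1, seed = 7)
  ft <- feature_table(co$memberships, covariates = co$covariates)
  tt <- two_sample_ttest(ft$ocr_state1[ft$group == 0],
                         ft$ocr_state1[ft$group == 1])
  expect_lt(tt$p, 0.01)
  expect_lt(tt$t, 0)  # patient analog occupies the target state more
})
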