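# Perturbation explainability: KLD, G2PC, P2D, ranking agreement.

test_that("kld matches closed forms and Gibbs' inequality", {
  expect_equal(kld(c(0.2, 0.3, 0.5), c(0.2, 0.3, 0.5)), 0)
  expect_equal(kld(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-6)
  expect_error(kld(c(-0.1, 1.1), c(0.5, 0.5)), "invalid distribution")
  set.seed(1)
  for (i in 1:25) {
    p <- runif(4); p <- p / sum(p)
    q <- runif(4); q <- q / sum(q)
    expect_gte(kld(p, q), 0)
  }
})

test_that("permute_feature shuffles one column without side effects", {
  set.seed(2)
  X <- matrix(rnorm(40), 10, 4)
  X_orig <- X
  Xp <- permute_feature(X, 2)
  expect_identical(X, X_orig)                      # input untouched
  expect_identical(Xp[, -2], X[, -2])              # other columns untouched
  expect_equal(sort(Xp[, 2]), sort(X[, 2]))        # multiset preserved
  expect_identical(permute_feature(X[1, , drop = FALSE], 1),
                   X[1, , drop = FALSE])           # N = 1 is a no-op
  Xc <- X; Xc[, 3] <- 7
  expect_identical(permute_feature(Xc, 3), Xc)     # constant column no-op
})

test_that("g2pc scores sit in [0,100], zero for constant features", {
  b <- make_blobs(n_per = 60, p = 4, gap = 6, sd = 0.5, seed = 3)
  x <- cbind(b$x, const = 1)
  fit <- fcm(x, K = 2, m = 2, seed = 0)
  g <- g2pc(x, fit, repeats = 5, seed = 1)
  expect_equal(dim(g), c(5, 5))
  expect_true(all(g >= 0 & g <= 100))
  expect_equal(unname(g[, 5]), rep(0, 5))
  # the only informative feature dominates the noise features
  expect_gt(mean(g[, 1]), 5 * max(colMeans(g[, 2:4, drop = FALSE])))
  # reproducible under seed
  expect_identical(g, g2pc(x, fit, repeats = 5, seed = 1))
})

test_that("p2d aggregates per-sample divergence correctly", {
  b <- make_blobs(n_per = 60, p = 3, gap = 6, sd = 0.5, seed = 4)
  x <- cbind(b$x, const = 2)
  fit <- fcm(x, K = 2, m = 2, seed = 0)
  res <- p2d(x, fit, repeats = 5, seed = 1)
  expect_s3_class(res, "p2d")
  expect_true(all(res$lp2d >= 0))
  expect_true(all(res$gp2d_total >= 0))
  # constant feature: exactly zero divergence everywhere
  expect_equal(unname(res$lp2d[, 4]), rep(0, 120))
  expect_equal(unname(res$gp2d_total[4]), 0)
  expect_equal(unname(res$gp2d_median[4]), 0)
  # total dominates the median for any nonnegative sample set of size >= 1
  expect_true(all(res$gp2d_total >= res$gp2d_median))
  # informative feature carries the largest divergence
  expect_equal(unname(which.max(res$gp2d_total)), 1L)
  expect_identical(res$lp2d, p2d(x, fit, repeats = 5, seed = 1)$lp2d)
})

test_that("every cluster switch implies strictly positive divergence", {
  pl <- make_planted_dfnc(n_subj = 3, T_win = 80, seed = 5)
  fit <- fcm(pl$X, K = 5, m = 2, seed = 0)
  U0 <- predict(fit, pl$X)
  lab0 <- hard_assign(U0)
  set.seed(6)
  for (f in c(1, 8, 21)) {
    Xp <- permute_feature(pl$X, f)
    U1 <- predict(fit, Xp)
    switched <- hard_assign(U1) != lab0
    d <- vapply(seq_len(nrow(U0)), function(i) kld(U0[i, ], U1[i, ]),
                numeric(1))
    expect_true(all(d[switched] > 0))
  }
})

test_that("pct_nonzero_lp2d is monotone in the threshold and 100% on continuous data", {
  pl <- make_planted_dfnc(n_subj = 4, T_win = 60, seed = 7)
  fit <- fcm(pl$X, K = 5, m = 2, seed = 0)
  res <- p2d(pl$X, fit, repeats = 3, seed = 2)
  pct0 <- pct_nonzero_lp2d(res)
  expect_equal(unname(pct0), rep(100, 21))
  pct_hi <- pct_nonzero_lp2d(res, threshold = 1e-3)
  expect_true(all(pct_hi <= pct0))
  zero <- res; zero$lp2d[] <- 0
  expect_equal(unname(pct_nonzero_lp2d(zero)), rep(0, 21))
})

test_that("compare_rankings agrees with a brute-force Kendall oracle", {
  expect_equal(compare_rankings(1:8, 1:8)$tau, 1)
  expect_equal(compare_rankings(1:8, 8:1)$tau, -1)
  r <- compare_rankings(c(1, 2, 3, 4), c(1, 2, 4, 3))
  expect_equal(r$tau, 2 / 3, tolerance = 1e-9)
  expect_equal(r$tau, kendall_oracle(c(1, 2, 3, 4), c(1, 2, 4, 3)))
  set.seed(8)
  for (i in 1:10) {
    a <- rnorm(7); b <- rnorm(7)
    expect_equal(compare_rankings(a, b)$tau, kendall_oracle(a, b),
                 tolerance = 1e-9)
  }
  expect_error(compare_rankings(rep(1, 5), 1:5), "all-tied")
})

test_that("the planted informative feature ranks first across repeats", {
  set.seed(9)
  first <- matrix(NA, 20, 3,
                  dimnames = list(NULL, c("g2pc", "total", "median")))
  for (r in 1:20) {
    n <- 80
    x <- matrix(rnorm(2 * n * 5, sd = 0.6), 2 * n, 5)
    x[seq_len(n), 1] <- x[seq_len(n), 1] + 6
    fit <- fcm(x, K = 2, m = 2, seed = r)
    g <- colMeans(g2pc(x, fit, repeats = 3, seed = r))
    p <- p2d(x, fit, repeats = 3, seed = r)
    first[r, ] <- c(which.max(g), which.max(p$gp2d_total),
                    which.max(p$gp2d_median)) == 1
  }
  expect_gte(mean(first[, "g2pc"]), 0.95)
  expect_gte(mean(first[, "total"]), 0.95)
  expect_gte(mean(first[, "median"]), 0.95)
})
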