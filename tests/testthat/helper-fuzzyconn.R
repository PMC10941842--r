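# Shared fixtures, built in code.

# Two well-separated Gaussian blobs in P dimensions, informative along the
# first coordinate only.
make_blobs <- function(n_per = 50, p = 2, gap = 6, sd = 0.5, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per * p, sd = sd), 2 * n_per, p)
  x[seq_len(n_per), 1] <- x[seq_len(n_per), 1] + gap
  list(x = x, centers = rbind(c(gap, rep(0, p - 1)), rep(0, p)))
}

# Small planted-state dFNC set: list(X, centroids, memberships).
make_planted_dfnc <- function(n_subj = 5, T_win = 100, K = 5, C = 7,
                              separation = 1.5, noise_sd = 0.1, seed = 3) {
  cent <- generate_centroids(K, C, separation, seed = seed)
  Us <- lapply(seq_len(n_subj), function(i)
    generate_membership_trajectories(T_win, K, seed = seed + i))
  dfnc <- generate_dfnc(Us, cent, noise_sd = noise_sd, seed = seed + 100)
  list(X = do.call(rbind, lapply(dfnc, `[[`, "values")),
       centroids = cent, memberships = Us, dfnc = dfnc)
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# Best-assignment cosine similarity between fitted and planted centroids:
# greedy maximum matching is enough at the similarity levels asserted.
matched_cosines <- function(fitted, planted) {
  S <- outer(seq_len(nrow(fitted)), seq_len(nrow(planted)),
             Vectorize(function(i, j) cosine(fitted[i, ], planted[j, ])))
  used <- integer(0)
  vapply(seq_len(nrow(planted)), function(j) {
    i <- setdiff(order(S[, j], decreasing = TRUE), used)[1]
    used <<- c(used, i)
    S[i, j]
  }, numeric(1))
}

# Brute-force BH step-up oracle.
bh_oracle <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- max(c(0L, which(ps <= seq_len(m) * alpha / m)))
  rej <- logical(m)
  if (k > 0) rej[o[seq_len(k)]] <- TRUE
  rej
}

# Brute-force Kendall tau over all pairs (no ties).
kendall_oracle <- function(a, b) {
  n <- length(a)
  s <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    s <- s + sign(a[j] - a[i]) * sign(b[j] - b[i])
  s / choose(n, 2)
}

# Small pipeline configuration for smoke tests.
smoke_config <- function(outdir, seed = 0L) {
  cfg <- default_config()
  cfg$paths$output_dir <- outdir
  cfg$simulate$n_group0 <- 10L
  cfg$simulate$n_group1 <- 10L
  cfg$simulate$T_win <- 40L
  cfg$simulate$n_sites <- 3L
  cfg$simulate$occupancy_effect <- 1.5
  cfg$simulate$symptom_effect <- 2
  cfg$simulate$seed <- seed
  cfg$clustering$m_grid <- c(1.5, 2)
  cfg$clustering$seed_grid <- 0:1
  cfg$explain$repeats <- 5L
  cfg$classify$folds <- 5L
  cfg$classify$inner_folds <- 3L
  cfg
}
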