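# Synthetic dFNC generator with planted ground truth.
#
# Every downstream stage (clustering, explainability, features, inference,
# classification) is validated against data whose states, membership
# trajectories and group effects are known by construction:
#   - K planted symmetric connectivity centroids (valid correlation patterns),
#   - per-subject smoothly varying row-stochastic membership trajectories
#     (smoothed Gaussian random walks pushed through a softmax),
#   - windows as noisy convex mixtures x(t) = sum_k u_k(t) c_k + eps(t),
#   - a two-group cohort with planted occupancy / transition effects and a
#     symptom score that is a stated linear function of one planted feature.

#' Generate planted state centroids
#'
#' Draws \code{K} vectorized symmetric connectivity patterns (strict
#' lower-triangle order, entries in \code{[-1, 1]}) by rejection sampling so
#' that every pair of centroids is at least \code{separation} apart in
#' Euclidean distance.
#'
#' @param K number of states.
#' @param C number of components (\code{P = C*(C-1)/2} features per centroid).
#' @param separation minimum pairwise Euclidean distance between centroids.
#' @param seed integer seed.
#' @param max_tries rejection-sampling budget per centroid.
#' @return \code{K x P} matrix, columns named by connectivity pair.
#' @export
generate_centroids <- function(K, C = 7, separation = 1.5, seed = 0,
                               max_tries = 2000) {
  stopifnot(K >= 1, C >= 2, separation > 0)
  P <- C * (C - 1) / 2
  with_seed(seed, {
    cent <- matrix(NA_real_, K, P)
    for (k in seq_len(K)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- stats::runif(P, -0.9, 0.9)
        if (k == 1 ||
            min(sqrt(rowSums((cent[seq_len(k - 1), , drop = FALSE] -
                                rep(cand, each = k - 1))^2))) >= separation) {
          cent[k, ] <- cand
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("generate_centroids: infeasible separation - could not place ",
             K, " centroids at separation ", separation)
    }
    colnames(cent) <- pair_labels(C)
    clip(cent)
  })
}

#' Generate a smooth row-stochastic membership trajectory
#'
#' \code{K} independent Gaussian random walks are smoothed with a moving
#' average of width \code{ceiling(smoothness)}, scaled by
#' \code{concentration}, and mapped through a row-wise softmax. Larger
#' \code{smoothness} gives smaller consecutive membership steps; larger
#' \code{concentration} pushes rows toward one-hot.
#'
#' @param T_win number of windows (rows).
#' @param K number of states.
#' @param smoothness moving-average width controlling temporal smoothness
#'   (default 10).
#' @param concentration logit scale controlling crispness (default 0.5; at
#'   trajectory lengths around 100-150 windows this gives dominant-state
#'   probabilities mostly in 0.7-0.98 with soft transitions, the shape
#'   typical of resting-state membership traces).
#' @param seed integer seed (NULL = use current RNG stream).
#' @param logit_bias optional length-\code{K} additive bias applied to the
#'   scaled logits before the softmax (used to plant occupancy effects).
#' @param step_sd innovation standard deviation of the random walks
#'   (default 1; larger values produce faster state switching).
#' @return \code{T_win x K} matrix with nonnegative rows summing to 1.
#' @export
generate_membership_trajectories <- function(T_win, K, smoothness = 10,
                                             concentration = 0.5, seed = NULL,
                                             logit_bias = NULL, step_sd = 1) {
  if (K < 1) stop("generate_membership_trajectories: empty state space")
  stopifnot(T_win >= 2, smoothness >= 0)
  with_seed(seed, {
    width <- max(1L, ceiling(smoothness))
    Z <- matrix(stats::rnorm(T_win * K, sd = step_sd), T_win, K)
    Z <- apply(Z, 2, cumsum)
    Z <- matrix(Z, T_win, K)
    if (width > 1) {
      kern <- rep(1 / width, width)
      Z <- apply(Z, 2, function(z)
        stats::filter(c(rep(z[1], width), z, rep(z[T_win], width)),
                      kern, sides = 2)[(width + 1):(width + T_win)])
    }
    Z <- concentration * Z
    if (!is.null(logit_bias)) Z <- sweep(Z, 2, logit_bias, "+")
    E <- exp(Z - apply(Z, 1, max))
    E / rowSums(E)
  })
}

#' Generate dFNC windows from planted states
#'
#' Each window is a noisy convex mixture of the planted centroids:
#' \eqn{x(t) = \sum_k u_k(t) c_k + \epsilon(t)} with i.i.d. Gaussian noise of
#' standard deviation \code{noise_sd} per entry. With \code{noise_sd = 0}
#' every window lies exactly in the convex hull of the centroids; with noise
#' the values are clipped back to \code{[-1, 1]} (they are correlations).
#'
#' @param memberships \code{T x K} row-stochastic matrix (or a list of them,
#'   one per subject).
#' @param centroids \code{K x P} matrix of planted states.
#' @param noise_sd nonnegative noise standard deviation.
#' @param seed integer seed.
#' @param subject_ids identifiers used when \code{memberships} is a list.
#' @return a single \code{dfnc_series} (matrix input) or a list of them.
#' @export
generate_dfnc <- function(memberships, centroids, noise_sd = 0.1, seed = 0,
                          subject_ids = NULL) {
  stopifnot(noise_sd >= 0)
  centroids <- as.matrix(centroids)
  one <- !is.list(memberships)
  if (one) memberships <- list(memberships)
  if (is.null(subject_ids))
    subject_ids <- sprintf("sub%03d", seq_along(memberships))
  out <- with_seed(seed, {
    lapply(seq_along(memberships), function(s) {
      U <- as.matrix(memberships[[s]])
      if (ncol(U) != nrow(centroids))
        stop("generate_dfnc: membership/centroid dimension mismatch")
      X <- U %*% centroids
      if (noise_sd > 0) {
        X <- X + matrix(stats::rnorm(length(X), sd = noise_sd),
                        nrow(X), ncol(X))
        X <- clip(X)
      }
      colnames(X) <- colnames(centroids)
      structure(list(subject_id = subject_ids[[s]], values = X,
                     pair_labels = colnames(centroids),
                     window = NULL, step = NA_integer_),
                class = "dfnc_series")
    })
  })
  if (one) out[[1]] else out
}

#' Generate component time series from correlation regimes
#'
#' Concatenates multivariate-Gaussian blocks, one per regime, each with its
#' own \code{C x C} covariance. Feeding the result through
#' \code{\link{extract_dfnc}} recovers the planted regime correlations,
#' giving an end-to-end test of the window pipeline.
#'
#' @param regimes list of \code{list(cov = <C x C PSD matrix>,
#'   duration = <frames>)}.
#' @param seed integer seed.
#' @return \code{frames x C} matrix.
#' @export
generate_component_timeseries <- function(regimes, seed = 0) {
  stopifnot(length(regimes) >= 1)
  C <- ncol(as.matrix(regimes[[1]]$cov))
  for (r in regimes) {
    S <- as.matrix(r$cov)
    if (!isTRUE(all.equal(S, t(S))) || min(eigen(S, symmetric = TRUE,
                                                 only.values = TRUE)$values) <
        -1e-8)
      stop("generate_component_timeseries: invalid covariance (not symmetric ",
           "positive semi-definite)")
  }
  with_seed(seed, {
    do.call(rbind, lapply(regimes, function(r)
      MASS::mvrnorm(r$duration, mu = rep(0, C), Sigma = as.matrix(r$cov))))
  })
}

#' Generate a two-group cohort with planted effects
#'
#' Builds per-subject membership trajectories and dFNC series for two groups
#' (group 0 = control analog, group 1 = patient analog), together with a
#' covariate table (age, gender, site, symptom scores). Effects are planted
#' on the generative side:
#' \describe{
#'   \item{occupancy}{group 1 receives an additive logit bias on
#'     \code{target_state} scaled so that the standardized mean difference of
#'     the subject-mean state logit equals \code{effect_spec$occupancy}.}
#'   \item{transition}{group 1's random-walk innovation SD is multiplied by
#'     \code{1 + effect_spec$transition / 2}, increasing switching rate.}
#'   \item{symptom}{the patient group's symptom score is
#'     \code{symptom_base + symptom_beta * z + N(0,1)} where \code{z} is the
#'     standardized subject-mean membership of \code{target_state}
#'     (\code{symptom_beta = effect_spec$symptom}); controls get \code{NA}.}
#' }
#' An empty \code{effect_spec} yields an exchangeable null cohort.
#'
#' @param n_group0,n_group1 group sizes (defaults 160 / 151, the usual
#'   control / patient cohort shape).
#' @param effect_spec named list with any of \code{occupancy},
#'   \code{transition}, \code{symptom} (numeric effect sizes).
#' @param T_win windows per subject (default 124).
#' @param K,C number of states / components (defaults 5, 7).
#' @param separation,noise_sd passed to the centroid and dFNC generators.
#' @param smoothness,concentration trajectory parameters
#'   (see \code{\link{generate_membership_trajectories}}).
#' @param n_sites number of acquisition sites (default 7).
#' @param target_state state carrying the occupancy / symptom effect
#'   (default 1).
#' @param symptom_base symptom-score intercept (default 15, a typical
#'   negative-symptom scale mean).
#' @param seed integer seed.
#' @return list with \code{dfnc} (list of \code{dfnc_series}),
#'   \code{memberships} (list of \code{T x K} matrices, the ground truth),
#'   \code{centroids}, \code{covariates} (data frame: subject_id, group, age,
#'   gender, site, panss_pos, panss_neg), and \code{effect_spec}.
#' @export
generate_cohort <- function(n_group0 = 160, n_group1 = 151,
                            effect_spec = list(), T_win = 124, K = 5, C = 7,
                            separation = 1.5, noise_sd = 0.1,
                            smoothness = 10, concentration = 0.5,
                            n_sites = 7, target_state = 1,
                            symptom_base = 15, seed = 0) {
  stopifnot(n_group0 >= 1, n_group1 >= 1)
  es <- function(nm) if (!is.null(effect_spec[[nm]])) effect_spec[[nm]] else 0
  stopifnot(all(vapply(effect_spec, is.finite, logical(1))))
  n <- n_group0 + n_group1
  group <- rep(c(0L, 1L), c(n_group0, n_group1))
  centroids <- generate_centroids(K, C, separation, seed = seed)

  with_seed(seed + 1L, {
    # raw (pre-bias) logit trajectories; the occupancy bias is calibrated
    # from their across-subject spread so the planted effect size is the
    # standardized mean difference on the subject-mean logit scale
    step_sd <- ifelse(group == 1L, 1 + es("transition") / 2, 1)
    raw <- lapply(seq_len(n), function(i)
      generate_membership_trajectories(T_win, K, smoothness, concentration,
                                       seed = NULL, step_sd = step_sd[i]))
    mean_logit <- vapply(raw, function(U) {
      L <- log(pmax(U, 1e-12))
      mean(L[, target_state] - rowMeans(L))
    }, numeric(1))
    bias <- es("occupancy") * stats::sd(mean_logit)
    memberships <- lapply(seq_len(n), function(i) {
      U <- raw[[i]]
      if (group[i] == 1L && bias != 0) {
        Z <- log(pmax(U, 1e-12))
        Z[, target_state] <- Z[, target_state] + bias
        E <- exp(Z - apply(Z, 1, max))
        U <- E / rowSums(E)
      }
      U
    })

    subject_ids <- sprintf("sub%03d", seq_len(n))
    age <- round(stats::rnorm(n, mean = 38, sd = 11), 1)
    gender <- stats::rbinom(n, 1, 0.75)            # 1 = male
    site <- sample(seq_len(n_sites), n, replace = TRUE)
    feat <- vapply(memberships, function(U) mean(U[, target_state]),
                   numeric(1))
    z <- (feat - mean(feat)) / stats::sd(feat)
    panss_neg <- ifelse(group == 1L,
                        symptom_base + es("symptom") * z + stats::rnorm(n),
                        NA_real_)
    panss_pos <- ifelse(group == 1L,
                        symptom_base + stats::rnorm(n, sd = 5), NA_real_)
    covariates <- data.frame(subject_id = subject_ids, group = group,
                             age = age, gender = gender,
                             site = factor(site),
                             panss_pos = round(panss_pos, 2),
                             panss_neg = round(panss_neg, 2),
                             stringsAsFactors = FALSE)

    dfnc <- generate_dfnc(memberships, centroids, noise_sd = noise_sd,
                          seed = seed + 2L, subject_ids = subject_ids)
    list(dfnc = dfnc, memberships = memberships, centroids = centroids,
         covariates = covariates, effect_spec = effect_spec)
  })
}
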