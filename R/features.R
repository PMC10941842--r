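# Dynamical and stability features from per-subject membership series.
#
# Traditional hard-cluster features (occupancy rate, number of state
# transitions) are computed from the argmax state sequence; the fuzzy
# features use the full membership probabilities: per-state descriptive
# statistics, cumulative change, entropy over time, consecutive-window KLD
# summaries, non-uniformity, and between-state correlations. LP2D stability
# features average each subject's per-window local divergence per
# connectivity pair.

#' Hard state assignment
#'
#' Argmax state per window; exact ties resolve to the lowest state index.
#'
#' @param U \code{T x K} membership matrix.
#' @return integer state sequence in \code{1..K}.
#' @export
hard_assign <- function(U) {
  U <- as.matrix(U)
  row_argmax(U)
}

#' Occupancy rate
#'
#' Percent of windows spent in each state; sums to 100.
#'
#' @param states integer state sequence in \code{1..K}.
#' @param K number of states.
#' @return length-\code{K} percentage vector.
#' @export
ocr <- function(states, K) {
  if (length(states) == 0) stop("ocr: empty state sequence")
  stopifnot(all(states >= 1), all(states <= K))
  100 * tabulate(states, nbins = K) / length(states)
}

#' Number of state transitions
#'
#' Count of consecutive windows whose hard assignment differs.
#'
#' @param states integer state sequence.
#' @return transition count in \code{0..(T-1)}.
#' @export
nst <- function(states) {
  stopifnot(length(states) >= 1)
  sum(diff(states) != 0)
}

#' Per-state membership descriptive statistics
#'
#' Mean, population variance, and range (max minus min) of each state's
#' membership trace over time: \code{3 * K} features.
#'
#' @param U \code{T x K} membership matrix.
#' @return named vector \code{mean_state<k>}, \code{variance_state<k>},
#'   \code{range_state<k>}.
#' @export
prob_stats <- function(U) {
  U <- as.matrix(U)
  Tn <- nrow(U); K <- ncol(U)
  mu <- colMeans(U)
  v <- colMeans(U^2) - mu^2
  rg <- apply(U, 2, max) - apply(U, 2, min)
  stats::setNames(c(mu, pmax(v, 0), rg),
                  c(paste0("mean_state", seq_len(K)),
                    paste0("variance_state", seq_len(K)),
                    paste0("range_state", seq_len(K))))
}

#' Cumulative membership change per state
#'
#' Sum of absolute consecutive changes of each state's membership trace:
#' \eqn{\sum_t |u_k(t) - u_k(t-1)|}.
#'
#' @param U \code{T x K} membership matrix, \code{T >= 2}.
#' @return named length-\code{K} vector.
#' @export
cumulative_difference <- function(U) {
  U <- as.matrix(U)
  if (nrow(U) < 2) stop("cumulative_difference: series too short (T < 2)")
  out <- colSums(abs(diff(U)))
  stats::setNames(out, paste0("cumulative_difference_state", seq_len(ncol(U))))
}

#' Shannon entropy of each state's membership trace over time
#'
#' Each state's trace is normalized to a distribution over time points,
#' \eqn{q_k(t) = u_k(t) / \sum_t u_k(t)}, and its entropy
#' \eqn{H_k = -\sum_t q_k(t) \log q_k(t)} (nats) is returned. A state
#' expressed evenly across the scan attains the maximum \eqn{\log T}; a
#' state concentrated in a few windows scores low.
#'
#' @param U \code{T x K} membership matrix with positive column sums.
#' @return named length-\code{K} vector in \code{[0, log T]}.
#' @export
entropy_over_time <- function(U) {
  U <- as.matrix(U)
  stopifnot(nrow(U) >= 1, all(colSums(U) > 0))
  H <- apply(U, 2, function(u) {
    q <- u / sum(u)
    q <- q[q > 0]
    -sum(q * log(q))
  })
  stats::setNames(H, paste0("entropy_state", seq_len(ncol(U))))
}

#' Summary statistics of consecutive-window membership divergence
#'
#' The KLD between each pair of consecutive membership rows,
#' \eqn{d(t) = D(u(t-1) \| u(t))}, summarized by its mean, median, standard
#' deviation, minimum and maximum: a five-number description of how abruptly
#' the state distribution moves.
#'
#' @param U \code{T x K} membership matrix, \code{T >= 2}.
#' @param eps KLD floor.
#' @return named vector \code{kld_mean}, \code{kld_median}, \code{kld_sd},
#'   \code{kld_min}, \code{kld_max}.
#' @export
consecutive_kld_stats <- function(U, eps = 1e-12) {
  U <- as.matrix(U)
  if (nrow(U) < 2) stop("consecutive_kld_stats: series too short (T < 2)")
  Tn <- nrow(U)
  same <- rowSums(U[-Tn, , drop = FALSE] != U[-1, , drop = FALSE]) == 0
  d <- row_kld(U[-Tn, , drop = FALSE], U[-1, , drop = FALSE], eps)
  d[same] <- 0
  c(kld_mean = mean(d), kld_median = stats::median(d),
    kld_sd = stats::sd(d), kld_min = min(d), kld_max = max(d))
}

#' Non-uniformity of each state's membership trace
#'
#' Mean squared deviation of the state's membership from the uniform level
#' \code{1/K}: \eqn{NU_k = (1/T) \sum_t (u_k(t) - 1/K)^2}. Zero when
#' memberships sit at the uniform level; large when the state is strongly
#' expressed or strongly suppressed.
#'
#' @param U \code{T x K} membership matrix.
#' @return named length-\code{K} vector.
#' @export
nonuniformity <- function(U) {
  U <- as.matrix(U)
  K <- ncol(U)
  out <- colMeans((U - 1 / K)^2)
  stats::setNames(out, paste0("nonuniformity_state", seq_len(K)))
}

#' Between-state membership correlations
#'
#' Pearson correlation between each pair of state membership traces
#' (\code{K*(K-1)/2} features), capturing which states trade probability
#' with which over time. A constant trace yields 0 for its pairs, with a
#' warning.
#'
#' @param U \code{T x K} membership matrix, \code{T >= 3}.
#' @return named vector \code{correlation_state<j>_state<k>}, \code{j < k}.
#' @export
state_correlations <- function(U) {
  U <- as.matrix(U)
  stopifnot(nrow(U) >= 3)
  K <- ncol(U)
  const <- apply(U, 2, function(u) stats::var(u) == 0)
  if (any(const))
    warning("state_correlations: constant membership trace; ",
            "its correlations set to 0")
  cm <- suppressWarnings(stats::cor(U))
  cm[is.na(cm)] <- 0
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  stats::setNames(cm[pairs],
                  paste0("correlation_state", pairs[, 1], "_state",
                         pairs[, 2]))
}

#' Per-subject LP2D stability features
#'
#' Averages the local per-window divergence map over each subject's windows,
#' giving one stability value per subject and connectivity pair (higher =
#' less stable to perturbation of that pair).
#'
#' @param lp2d \code{N x P} per-window LP2D matrix (windows pooled across
#'   subjects).
#' @param subject factor/vector of length \code{N} mapping each window to
#'   its subject.
#' @return \code{n_subjects x P} matrix, rows named by subject, columns
#'   \code{lp2d_<pair>}.
#' @export
lp2d_subject_features <- function(lp2d, subject) {
  lp2d <- as.matrix(lp2d)
  if (length(subject) != nrow(lp2d) || anyNA(subject))
    stop("lp2d_subject_features: every window must map to exactly one subject")
  subject <- factor(subject, levels = unique(subject))
  out <- rowsum(lp2d, subject) / as.vector(table(subject))
  colnames(out) <- paste0("lp2d_", gsub("/", "_", colnames(lp2d)))
  out
}

#' Extract the full per-subject feature vector
#'
#' All dynamical features from one membership series: occupancy rates and
#' transition count, non-uniformity, consecutive-KLD summaries, entropy,
#' descriptive statistics, cumulative change, and state correlations.
#'
#' @param U \code{T x K} membership matrix.
#' @param eps KLD floor.
#' @return named numeric vector.
#' @seealso \code{\link{feature_table}} for a whole cohort.
#' @export
subject_features <- function(U, eps = 1e-12) {
  U <- as.matrix(U)
  K <- ncol(U)
  states <- hard_assign(U)
  c(stats::setNames(ocr(states, K), paste0("ocr_state", seq_len(K))),
    nst = nst(states),
    nonuniformity(U),
    consecutive_kld_stats(U, eps),
    entropy_over_time(U),
    prob_stats(U),
    cumulative_difference(U),
    state_correlations(U))
}

#' Feature families
#'
#' Maps each feature name produced by \code{\link{subject_features}} (and the
#' LP2D stability features) to its family, the unit at which FDR correction
#' and per-family classification operate: \code{nst_ocr},
#' \code{nonuniformity_kld_entropy}, \code{average}, \code{variance},
#' \code{range}, \code{correlation}, \code{cumulative_difference},
#' \code{lp2d}.
#'
#' @param feature_names character vector of feature column names.
#' @return named character vector (feature -> family).
#' @export
feature_families <- function(feature_names) {
  fam <- ifelse(grepl("^(ocr_|nst$)", feature_names), "nst_ocr",
         ifelse(grepl("^(nonuniformity_|kld_|entropy_)", feature_names),
                "nonuniformity_kld_entropy",
         ifelse(grepl("^mean_", feature_names), "average",
         ifelse(grepl("^variance_", feature_names), "variance",
         ifelse(grepl("^range_", feature_names), "range",
         ifelse(grepl("^correlation_", feature_names), "correlation",
         ifelse(grepl("^cumulative_difference_", feature_names),
                "cumulative_difference",
         ifelse(grepl("^lp2d_", feature_names), "lp2d", NA_character_))))))))
  if (anyNA(fam))
    stop("feature_families: unrecognized feature name(s): ",
         paste(feature_names[is.na(fam)], collapse = ", "))
  stats::setNames(fam, feature_names)
}

#' Build the cohort feature table
#'
#' One row per subject: all dynamical features from the subject's membership
#' series, optional LP2D stability features, and (if given) the covariate
#' columns joined by subject id.
#'
#' @param memberships list of per-subject \code{T x K} membership matrices,
#'   named by subject id (unnamed lists get \code{sub001, ...}).
#' @param lp2d optional \code{N x P} pooled LP2D matrix.
#' @param subject optional length-\code{N} window-to-subject map (required
#'   with \code{lp2d}).
#' @param covariates optional data frame with a \code{subject_id} column.
#' @param eps KLD floor.
#' @return data frame with \code{subject_id}, feature columns, and covariate
#'   columns; the feature-to-family map is attached as
#'   \code{attr(, "families")}.
#' @export
feature_table <- function(memberships, lp2d = NULL, subject = NULL,
                          covariates = NULL, eps = 1e-12) {
  ids <- names(memberships)
  if (is.null(ids)) ids <- sprintf("sub%03d", seq_along(memberships))
  feats <- t(vapply(memberships, subject_features,
                    subject_features(memberships[[1]], eps), eps = eps))
  rownames(feats) <- ids
  if (!is.null(lp2d)) {
    if (is.null(subject))
      stop("feature_table: `subject` map required with lp2d")
    lf <- lp2d_subject_features(lp2d, subject)
    feats <- cbind(feats, lf[ids, , drop = FALSE])
  }
  out <- data.frame(subject_id = ids, feats, row.names = NULL,
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(covariates))
    out <- merge(out, covariates, by = "subject_id", sort = FALSE)
  attr(out, "families") <- feature_families(colnames(feats))
  out
}
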