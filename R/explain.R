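# Perturbation-based explainability for the fitted fuzzy clustering.
#
# G2PC permutes one feature at a time and reports the percentage of samples
# whose hard (argmax) cluster assignment switches. P2D replaces the hard
# switch count with the Kullback-Leibler divergence between each sample's
# membership distribution before versus after permutation, giving global
# summaries (total and median KLD across samples: GP2D) and a local
# per-sample map (LP2D) that registers the effect of perturbation on every
# sample, not just the minority that switch clusters.

#' Kullback-Leibler divergence between two probability vectors
#'
#' \eqn{D(p \| q) = \sum_k p_k \log(p_k / q_k)} in nats, after flooring both
#' vectors at \code{eps} and renormalizing (fuzzy memberships are strictly
#' positive in exact arithmetic but can underflow).
#'
#' @param p,q probability vectors of equal length, each summing to 1.
#' @param eps floor applied before renormalization (default 1e-12).
#' @return nonnegative divergence; exactly 0 when \code{p == q}.
#' @examples
#' kld(c(1, 0), c(0.5, 0.5))  # log(2)
#' @export
kld <- function(p, q, eps = 1e-12) {
  stopifnot(length(p) == length(q))
  if (any(p < 0) || any(q < 0)) stop("kld: invalid distribution (negative entries)")
  if (identical(as.numeric(p), as.numeric(q))) return(0)
  p <- pmax(p, eps); p <- p / sum(p)
  q <- pmax(q, eps); q <- q / sum(q)
  sum(p * log(p / q))
}

# Row-wise KLD between two matrices of membership rows (vectorized kld).
row_kld <- function(P, Q, eps = 1e-12) {
  P <- pmax(P, eps); P <- P / rowSums(P)
  Q <- pmax(Q, eps); Q <- Q / rowSums(Q)
  rowSums(P * (log(P) - log(Q)))
}

#' Permute one feature column
#'
#' Shuffles column \code{f} across samples, leaving all other columns
#' untouched; the input is not modified.
#'
#' @param X \code{N x P} matrix.
#' @param f feature index in \code{1..P}.
#' @return the permuted copy of \code{X}.
#' @export
permute_feature <- function(X, f) {
  stopifnot(f >= 1, f <= ncol(X))
  X[, f] <- X[sample.int(nrow(X)), f]
  X
}

#' Global permutation percent change (G2PC)
#'
#' For each repeat and each feature: permute the feature across samples,
#' recompute fuzzy memberships against the fitted centroids, hard-assign by
#' argmax before and after, and report the percentage of samples whose
#' assignment switches. Features causing the most switching are the most
#' important to the clustering.
#'
#' @param X \code{N x P} data matrix the model explains.
#' @param model fitted \code{\link{fcm}} model on the same feature space.
#' @param repeats number of fresh permutations per feature (default 30).
#' @param seed integer seed.
#' @return \code{repeats x P} matrix of percent-switched values in
#'   \code{[0, 100]}, columns named by feature.
#' @export
g2pc <- function(X, model, repeats = 30, seed = 0) {
  X <- as.matrix(X)
  base_lab <- row_argmax(predict(model, X))
  P <- ncol(X)
  with_seed(seed, {
    out <- matrix(NA_real_, repeats, P)
    colnames(out) <- colnames(X)
    for (r in seq_len(repeats)) {
      for (f in seq_len(P)) {
        lab <- row_argmax(predict(model, permute_feature(X, f)))
        out[r, f] <- 100 * mean(lab != base_lab)
      }
    }
    out
  })
}

#' Permutation-based distribution divergence (P2D)
#'
#' For each repeat, feature and sample, computes the KLD between the sample's
#' membership distribution before and after permuting that feature
#' (direction: before relative to after). Aggregates:
#' \describe{
#'   \item{lp2d}{\code{N x P} per-sample mean KLD over repeats (local map).}
#'   \item{gp2d_total}{per-feature mean over repeats of the KLD summed over
#'     samples.}
#'   \item{gp2d_median}{per-feature mean over repeats of the KLD median over
#'     samples.}
#' }
#'
#' @param X,model,repeats,seed as in \code{\link{g2pc}}.
#' @param eps KLD floor (default 1e-12).
#' @return object of class \code{"p2d"}: list with \code{lp2d},
#'   \code{gp2d_total}, \code{gp2d_median}, \code{feature_ids},
#'   \code{repeats}, \code{seed}.
#' @export
p2d <- function(X, model, repeats = 30, seed = 0, eps = 1e-12) {
  X <- as.matrix(X)
  N <- nrow(X); P <- ncol(X)
  U0 <- predict(model, X)
  with_seed(seed, {
    lp2d <- matrix(0, N, P)
    tot <- med <- matrix(NA_real_, repeats, P)
    for (r in seq_len(repeats)) {
      for (f in seq_len(P)) {
        U1 <- predict(model, permute_feature(X, f))
        d <- row_kld(U0, U1, eps)
        d[apply(U0 == U1, 1, all)] <- 0   # untouched rows diverge exactly 0
        lp2d[, f] <- lp2d[, f] + d
        tot[r, f] <- sum(d)
        med[r, f] <- stats::median(d)
      }
    }
    lp2d <- lp2d / repeats
    colnames(lp2d) <- colnames(tot) <- colnames(med) <- colnames(X)
    structure(list(lp2d = lp2d,
                   gp2d_total = colMeans(tot),
                   gp2d_median = colMeans(med),
                   feature_ids = colnames(X),
                   repeats = as.integer(repeats),
                   seed = as.integer(seed)),
              class = "p2d")
  })
}

#' @export
print.p2d <- function(x, ...) {
  cat("P2D importance:", nrow(x$lp2d), "samples x", ncol(x$lp2d),
      "features,", x$repeats, "repeats\n")
  ord <- order(x$gp2d_total, decreasing = TRUE)
  top <- utils::head(ord, 5)
  cat("  top features by total GP2D:",
      paste(sprintf("%s (%.3g)", x$feature_ids[top], x$gp2d_total[top]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Percentage of samples with non-zero local divergence
#'
#' Per feature, the percentage of samples whose mean per-sample KLD (LP2D)
#' exceeds \code{threshold}. On continuous data this is 100 percent for every
#' feature — permutation perturbs every sample's membership distribution —
#' whereas hard switching (G2PC) registers only a minority of samples.
#'
#' @param result a \code{\link{p2d}} result.
#' @param threshold nonnegative cut-off (default 0).
#' @return named per-feature percentage vector.
#' @export
pct_nonzero_lp2d <- function(result, threshold = 0) {
  stopifnot(inherits(result, "p2d"), threshold >= 0)
  100 * colMeans(result$lp2d > threshold)
}

#' Compare two importance rankings
#'
#' Kendall's rank correlation (tau) with a two-sided p-value between two
#' per-feature importance score vectors; agreement in rank indicates that
#' the methods attribute importance consistently.
#'
#' @param scores_a,scores_b numeric vectors of equal length (>= 2).
#' @return list with \code{tau} and \code{p}.
#' @export
compare_rankings <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) == length(scores_b), length(scores_a) >= 2)
  if (stats::var(scores_a) == 0 || stats::var(scores_b) == 0)
    stop("compare_rankings: undefined tau for an all-tied score vector")
  ct <- suppressWarnings(stats::cor.test(scores_a, scores_b,
                                         method = "kendall"))
  list(tau = unname(ct$estimate), p = ct$p.value)
}
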