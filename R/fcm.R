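# Fuzzy c-means clustering of dFNC windows.
#
# Unlike k-means, fuzzy c-means (FCM) assigns every sample a probability
# (membership) of belonging to each cluster, governed by the fuzziness
# exponent m > 1 (m -> 1 recovers hard k-means). The model is selected by
# maximizing the fuzzy partition coefficient (FPC) over a grid of m and
# initialization seeds.

#' Fit a fuzzy c-means model
#'
#' Alternating-optimization FCM: memberships
#' \eqn{u_{ij} = 1 / \sum_l (d_{ij}/d_{il})^{2/(m-1)}} with Euclidean
#' distances \eqn{d}, centroids
#' \eqn{c_j = \sum_i u_{ij}^m x_i / \sum_i u_{ij}^m}, iterated from a random
#' row-stochastic membership matrix until the largest membership change falls
#' below \code{tol} or \code{max_iter} is reached. The objective
#' \eqn{J_m = \sum_{ij} u_{ij}^m d_{ij}^2} is non-increasing across
#' iterations (checked during the fit). A sample at exactly zero distance
#' from a centroid receives membership 1 on that centroid.
#'
#' @param X numeric \code{N x P} data matrix (rows = samples).
#' @param K number of clusters (\code{1 <= K < N}); default 5, the usual
#'   choice for dFNC state analysis.
#' @param m fuzziness exponent, \code{> 1} (default 2).
#' @param seed integer seed for the random membership initialization.
#' @param tol convergence tolerance on \code{max |delta u|} (default 1e-6).
#' @param max_iter iteration cap (default 1000).
#' @return object of class \code{"fcm"}: list with \code{centroids}
#'   (\code{K x P}), \code{memberships} (\code{N x K}, rows sum to 1),
#'   \code{m}, \code{K}, \code{fpc}, \code{objective} (per-iteration
#'   \eqn{J_m}), \code{n_iter}, \code{converged}, \code{seed}, \code{call}.
#' @seealso \code{\link{predict.fcm}}, \code{\link{fpc}},
#'   \code{\link{fcm_select}}
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(100, 0), 50), matrix(rnorm(100, 5), 50))
#' fit <- fcm(X, K = 2, seed = 1)
#' fit
#' @export
fcm <- function(X, K = 5, m = 2, seed = 0, tol = 1e-6, max_iter = 1000) {
  X <- as.matrix(X)
  N <- nrow(X)
  if (m <= 1) stop("fcm: invalid fuzziness, m must be > 1")
  stopifnot(K >= 1, N > K)
  cl <- match.call()

  for (attempt in 1:2) {
    U <- with_seed(seed + (attempt - 1L) * 104729L, {
      u <- matrix(stats::runif(N * K), N, K)
      u / rowSums(u)
    })
    fit <- fcm_iterate(X, U, m, tol, max_iter)
    if (!fit$degenerate) break
    if (attempt == 2) stop("fcm: degenerate fit (collapsed centroids) after ",
                           "re-initialization")
  }

  structure(list(centroids = fit$centroids, memberships = fit$U,
                 m = m, K = as.integer(K), fpc = fpc(fit$U),
                 objective = fit$objective, n_iter = fit$n_iter,
                 converged = fit$converged, seed = as.integer(seed),
                 call = cl),
            class = "fcm")
}

# One full alternating-optimization run from membership matrix U.
fcm_iterate <- function(X, U, m, tol, max_iter) {
  N <- nrow(X); K <- ncol(U)
  objective <- numeric(0)
  converged <- FALSE
  centroids <- NULL
  for (it in seq_len(max_iter)) {
    Um <- U^m
    centroids <- (t(Um) %*% X) / colSums(Um)
    if (anyNA(centroids))
      return(list(degenerate = TRUE))
    # collapsed (duplicate) centroids make memberships ill-defined
    if (K > 1 && min(stats::dist(centroids)) < 1e-12)
      return(list(degenerate = TRUE))
    D2 <- sq_dist(X, centroids)
    J <- sum(Um * D2)
    if (length(objective) && J > objective[length(objective)] + 1e-8 * abs(J))
      warning("fcm: objective increased at iteration ", it)
    objective <- c(objective, J)
    U_new <- membership_update(D2, m)
    delta <- max(abs(U_new - U))
    U <- U_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(centroids = centroids, U = U, objective = objective,
       n_iter = length(objective), converged = converged, degenerate = FALSE)
}

# Squared Euclidean distances between rows of X (N x P) and C (K x P).
sq_dist <- function(X, C) {
  d2 <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * X %*% t(C)
  pmax(d2, 0)
}

# FCM membership update from squared distances; zero distance => one-hot.
membership_update <- function(D2, m) {
  N <- nrow(D2); K <- ncol(D2)
  U <- matrix(0, N, K)
  zero <- D2 < .Machine$double.eps
  has_zero <- rowSums(zero) > 0
  if (any(has_zero)) {
    z <- zero[has_zero, , drop = FALSE]
    U[has_zero, ] <- z / rowSums(z)
  }
  if (any(!has_zero)) {
    d <- D2[!has_zero, , drop = FALSE]^(-1 / (m - 1))  # d_ij^(-2/(m-1))
    U[!has_zero, ] <- d / rowSums(d)
  }
  U
}

#' Predict fuzzy memberships for new samples
#'
#' A single membership update against the fitted (frozen) centroids.
#'
#' @param object fitted \code{\link{fcm}} model.
#' @param newdata numeric \code{N x P} matrix with \code{P} matching the fit.
#' @param ... unused.
#' @return \code{N x K} membership matrix, rows summing to 1.
#' @export
predict.fcm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$centroids))
    stop("predict.fcm: newdata has ", ncol(newdata),
         " columns; model was fitted on ", ncol(object$centroids))
  membership_update(sq_dist(newdata, object$centroids), object$m)
}

#' @export
fitted.fcm <- function(object, ...) object$memberships

#' @export
coef.fcm <- function(object, ...) object$centroids

#' @export
print.fcm <- function(x, ...) {
  cat("Fuzzy c-means model\n")
  cat("  K =", x$K, " m =", format(x$m), " seed =", x$seed, "\n")
  cat("  N =", nrow(x$memberships), "samples,", ncol(x$centroids),
      "features\n")
  cat("  FPC =", format(x$fpc, digits = 4),
      sprintf("(uniform floor 1/K = %.3f)\n", 1 / x$K))
  cat("  ", x$n_iter, " iterations, ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  invisible(x)
}

#' @export
summary.fcm <- function(object, ...) {
  hard <- row_argmax(object$memberships)
  out <- list(model = object,
              hard_counts = tabulate(hard, nbins = object$K),
              mean_max_membership = mean(apply(object$memberships, 1, max)))
  class(out) <- "summary.fcm"
  out
}

#' @export
print.summary.fcm <- function(x, ...) {
  print(x$model)
  cat("  hard-assignment counts:", paste(x$hard_counts, collapse = ", "), "\n")
  cat("  mean max membership:", format(x$mean_max_membership, digits = 4),
      "\n")
  invisible(x)
}

#' Plot fuzzy-state centroids as connectivity matrices
#'
#' Draws each centroid as a \code{C x C} connectivity heatmap (the inverse of
#' the pairwise vectorization), sharing one color scale across states.
#'
#' @param x fitted \code{\link{fcm}} model whose feature space is a vectorized
#'   \code{C x C} connectivity matrix.
#' @param C number of components; inferred from \code{P = C*(C-1)/2} if
#'   missing.
#' @param ... passed to \code{image}.
#' @export
plot.fcm <- function(x, C = NULL, ...) {
  P <- ncol(x$centroids)
  if (is.null(C)) C <- round((1 + sqrt(1 + 8 * P)) / 2)
  if (C * (C - 1) / 2 != P)
    stop("plot.fcm: feature count ", P, " is not a C*(C-1)/2 pair count")
  K <- x$K
  old <- graphics::par(mfrow = c(1, K), mar = c(2, 2, 2, 1))
  on.exit(graphics::par(old))
  zlim <- c(-1, 1) * max(abs(x$centroids), 1e-9)
  pal <- grDevices::hcl.colors(65, "Blue-Red 2")
  for (k in seq_len(K)) {
    m <- unvectorize(x$centroids[k, ], C)
    graphics::image(seq_len(C), seq_len(C), m[, C:1], zlim = zlim, col = pal,
                    xlab = "", ylab = "", main = paste("State", k), ...)
  }
  invisible(x)
}

#' Fuzzy partition coefficient
#'
#' \eqn{FPC = (1/N) \sum_i \sum_j u_{ij}^2}, a crispness score in
#' \code{[1/K, 1]}: 1 for one-hot memberships, \code{1/K} for uniform ones.
#' Used to select the fuzziness exponent and initialization seed.
#'
#' @param U \code{N x K} membership matrix (rows sum to 1) or an \code{fcm}
#'   fit.
#' @return FPC value.
#' @examples
#' fpc(rbind(c(0.5, 0.5), c(0.8, 0.2)))  # 0.59
#' @export
fpc <- function(U) {
  if (inherits(U, "fcm")) U <- U$memberships
  U <- as.matrix(U)
  if (nrow(U) == 0) stop("fpc: empty membership matrix")
  sum(U^2) / nrow(U)
}

#' Select a fuzzy c-means model by FPC grid search
#'
#' Fits every combination of fuzziness \code{m_grid} and initialization seed
#' \code{seed_grid} and returns the fit with the largest fuzzy partition
#' coefficient; ties break toward smaller \code{m}, then smaller seed. The
#' full grid table is attached as \code{$grid}.
#'
#' @param X data matrix.
#' @param K number of clusters.
#' @param m_grid candidate fuzziness values (default
#'   \code{c(1.1, 1.3, 1.5, 1.7, 2, 2.5)}).
#' @param seed_grid candidate seeds (default \code{0:9}).
#' @param tol,max_iter passed to \code{\link{fcm}}.
#' @param verbose print the grid table as it is computed.
#' @return the selected \code{fcm} fit, with a \code{grid} data frame
#'   (\code{m}, \code{seed}, \code{fpc}, \code{converged}) attached.
#' @export
fcm_select <- function(X, K = 5, m_grid = c(1.1, 1.3, 1.5, 1.7, 2, 2.5),
                       seed_grid = 0:9, tol = 1e-6, max_iter = 1000,
                       verbose = FALSE) {
  stopifnot(length(m_grid) >= 1, length(seed_grid) >= 1)
  grid <- expand.grid(m = m_grid, seed = seed_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$m, grid$seed), , drop = FALSE]
  fits <- vector("list", nrow(grid))
  grid$fpc <- NA_real_
  grid$converged <- NA
  for (i in seq_len(nrow(grid))) {
    fit <- tryCatch(fcm(X, K = K, m = grid$m[i], seed = grid$seed[i],
                        tol = tol, max_iter = max_iter),
                    error = function(e) NULL)
    fits[[i]] <- fit
    if (!is.null(fit)) {
      grid$fpc[i] <- fit$fpc
      grid$converged[i] <- fit$converged
    }
    if (verbose)
      message(sprintf("m=%.2f seed=%d fpc=%s", grid$m[i], grid$seed[i],
                      ifelse(is.na(grid$fpc[i]), "degenerate",
                             format(grid$fpc[i], digits = 5))))
  }
  if (all(is.na(grid$fpc))) stop("fcm_select: all fits degenerate")
  # grid is sorted by (m, seed); which.max takes the first maximum, which
  # realises the smaller-m-then-smaller-seed tie-break.
  best <- which.max(grid$fpc)
  out <- fits[[best]]
  rownames(grid) <- NULL
  out$grid <- grid
  out
}
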