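# Internal helpers shared across modules.

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library code never clobbers the user's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Connectivity pair labels
#'
#' Labels for the vectorized strict lower triangle of a \code{C x C}
#' connectivity matrix, traversed row-wise: (2,1), (3,1), (3,2), (4,1), ...
#' Labels follow the convention \code{"IC<i>/IC<j>"} with \code{i > j};
#' \code{IC1/IC2} and \code{IC2/IC1} name the same pair.
#'
#' @param C number of components (\code{C >= 2}).
#' @return character vector of length \code{C*(C-1)/2}.
#' @examples
#' pair_labels(3)  # "IC2/IC1" "IC3/IC1" "IC3/IC2"
#' @export
pair_labels <- function(C) {
  stopifnot(C >= 2)
  idx <- pair_index(C)
  paste0("IC", idx[, 1], "/IC", idx[, 2])
}

# Row-wise strict lower triangle index pairs (i > j), 1-based.
pair_index <- function(C) {
  i <- rep(seq_len(C), times = seq_len(C) - 1L)
  j <- unlist(lapply(seq_len(C), function(r) seq_len(r - 1L)), use.names = FALSE)
  cbind(i = i, j = j)
}

#' Vectorize / restore a symmetric connectivity matrix
#'
#' \code{vectorize} maps a symmetric \code{C x C} matrix to its strict lower
#' triangle traversed row-wise; \code{unvectorize} inverts the map, restoring
#' the diagonal as 1 (a correlation matrix's self-connectivity).
#'
#' @param mat symmetric numeric matrix.
#' @param vec numeric vector of length \code{C*(C-1)/2}.
#' @param C number of components.
#' @param tol symmetry tolerance for \code{vectorize}.
#' @return \code{vectorize}: numeric vector; \code{unvectorize}: symmetric
#'   matrix with unit diagonal.
#' @export
vectorize <- function(mat, tol = 1e-9) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  if (max(abs(mat - t(mat))) > tol)
    stop("vectorize: input matrix is not symmetric (asymmetry)")
  idx <- pair_index(nrow(mat))
  out <- mat[idx]
  names(out) <- pair_labels(nrow(mat))
  out
}

#' @rdname vectorize
#' @export
unvectorize <- function(vec, C) {
  stopifnot(length(vec) == C * (C - 1) / 2)
  m <- diag(1, C)
  idx <- pair_index(C)
  m[idx] <- vec
  m[idx[, c(2, 1), drop = FALSE]] <- vec
  m
}

clip <- function(x, lo = -1, hi = 1) pmin(pmax(x, lo), hi)

# argmax with ties broken toward the lowest index (which.max's behaviour).
row_argmax <- function(U) max.col(U, ties.method = "first")
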