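# Tapered sliding-window dFNC extraction.
#
# Dynamic functional network connectivity (dFNC) is the windowed Pearson
# correlation between pairs of component time courses. The window is a
# rectangle convolved with a Gaussian taper, the field-standard choice for
# resting-state fMRI (rectangle of 20 TRs = 40 s at TR = 2 s, Gaussian
# sigma = 3 TRs).

#' Construct a tapered sliding window
#'
#' Builds the weight vector of a rectangular window convolved with a Gaussian
#' kernel sampled at integer TR offsets in \code{[-truncation, truncation]},
#' normalized to sum to 1. With \code{sigma = 0} the Gaussian degenerates to a
#' delta and the result is a plain normalized rectangle (zero-padded if
#' \code{truncation > 0}).
#'
#' @param rect_len rectangle length in TRs (default 20, i.e. 40 s at TR = 2 s).
#' @param sigma Gaussian standard deviation in TRs (default 3).
#' @param truncation Gaussian support half-width in TRs; the window length is
#'   \code{rect_len + 2 * truncation} (default 7, so the default window spans
#'   34 TRs).
#' @return object of class \code{"tapered_window"}: a list with \code{weights}
#'   (length \code{rect_len + 2*truncation}, summing to 1, symmetric),
#'   \code{rect_len}, \code{sigma}, \code{truncation}.
#' @examples
#' w <- make_tapered_window(20, 3, 7)
#' length(w$weights)  # 34
#' sum(w$weights)     # 1
#' @export
make_tapered_window <- function(rect_len = 20, sigma = 3, truncation = 7) {
  stopifnot(rect_len >= 2, sigma >= 0, truncation >= 0)
  L <- rect_len + 2L * truncation
  rect <- rep(1, rect_len)
  if (sigma == 0) {
    w <- c(rep(0, truncation), rect, rep(0, truncation))
  } else {
    offs <- seq(-truncation, truncation)
    g <- exp(-offs^2 / (2 * sigma^2))
    # full discrete convolution of rect (rect_len) with g (2*truncation + 1)
    w <- as.numeric(stats::convolve(c(rect, rep(0, length(g) - 1)),
                                    rev(g), type = "open"))[seq_len(L)]
  }
  w <- w / sum(w)
  structure(list(weights = w, rect_len = as.integer(rect_len),
                 sigma = sigma, truncation = as.integer(truncation)),
            class = "tapered_window")
}

#' Weighted Pearson correlation
#'
#' Pearson correlation with observation weights \code{w} (nonnegative, summing
#' to 1): means, variances and covariance are all weighted. With uniform
#' weights this reduces to the ordinary Pearson correlation.
#'
#' @param x,y numeric vectors of equal length.
#' @param w nonnegative weights summing to 1.
#' @return correlation in \code{[-1, 1]}; if either series has zero weighted
#'   variance, returns 0 with a warning (degenerate window).
#' @export
weighted_pearson <- function(x, y, w) {
  stopifnot(length(x) == length(y), length(x) == length(w), length(x) >= 2,
            all(w >= 0))
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx <= 0 || vy <= 0) {
    warning("weighted_pearson: zero weighted variance in window; returning 0")
    return(0)
  }
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}

#' Extract tapered sliding-window dFNC
#'
#' Slides the tapered window along the component time series and computes, at
#' each position, the weighted Pearson correlation of every component pair.
#' Pair columns follow the strict lower triangle traversed row-wise (see
#' \code{\link{pair_labels}}). With 7 components this yields 21 pair features;
#' 157 frames with the default 34-TR window and step 1 yield 124 windows.
#'
#' @param ts numeric \code{frames x C} matrix of component time courses.
#' @param window a \code{\link{make_tapered_window}} object.
#' @param step slide step in TRs (default 1).
#' @param subject_id identifier stored on the result.
#' @return object of class \code{"dfnc_series"}: list with \code{values}
#'   (\code{T x P} matrix, \code{P = C*(C-1)/2}, columns named by pair),
#'   \code{pair_labels}, \code{subject_id}, \code{window}, \code{step}.
#' @export
extract_dfnc <- function(ts, window = make_tapered_window(), step = 1,
                         subject_id = "subject") {
  ts <- as.matrix(ts)
  L <- length(window$weights)
  frames <- nrow(ts); C <- ncol(ts)
  if (frames < L)
    stop("extract_dfnc: series too short (", frames, " frames < window length ",
         L, ")")
  stopifnot(step >= 1, C >= 2)
  starts <- seq(1L, frames - L + 1L, by = step)
  idx <- pair_index(C)
  wts <- window$weights / sum(window$weights)
  vals <- matrix(NA_real_, nrow = length(starts), ncol = nrow(idx))
  degenerate <- FALSE
  for (t in seq_along(starts)) {
    seg <- ts[starts[t]:(starts[t] + L - 1L), , drop = FALSE]
    cw <- suppressWarnings(stats::cov.wt(seg, wt = wts, cor = TRUE,
                                         method = "ML"))
    cm <- cw$cor
    if (anyNA(cm)) {
      degenerate <- TRUE
      cm[is.na(cm)] <- 0
      diag(cm) <- 1
    }
    vals[t, ] <- cm[idx]
  }
  if (degenerate)
    warning("extract_dfnc: degenerate (zero-variance) window encountered; ",
            "affected correlations set to 0")
  colnames(vals) <- pair_labels(C)
  structure(list(subject_id = subject_id, values = vals,
                 pair_labels = pair_labels(C), window = window,
                 step = as.integer(step)),
            class = "dfnc_series")
}

#' @export
print.dfnc_series <- function(x, ...) {
  cat("dFNC series: subject", x$subject_id, "-", nrow(x$values), "windows x",
      ncol(x$values), "pairs\n")
  invisible(x)
}
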