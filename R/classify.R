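# Per-family elastic-net logistic classification with nested CV.
#
# Label convention: 0 = patient analog, 1 = control analog. The model
# predicts P(y = 1), so a negative coefficient means that an increase in the
# feature increases the likelihood of the patient class. Sensitivity is the
# true-positive rate for the patient class (label 0 remapped as positive for
# metric computation); specificity is the control true-negative rate.
# AUC/SENS/SPEC are reported on the 0-100 scale.

#' Nested cross-validated elastic-net logistic regression
#'
#' Outer stratified k-fold; within each outer training set the features are
#' z-scored with training statistics only, and an inner stratified k-fold
#' grid search over the L1 ratio and regularization strength maximizes inner
#' AUC. The winning pair is refit on the full outer-training set and
#' evaluated on the outer test fold: AUC, plus sensitivity and specificity
#' at a 0.5 probability threshold.
#'
#' @param x numeric \code{n x p} feature matrix (one family's columns).
#' @param y labels in \code{\{0, 1\}} (0 = patient analog, 1 = control
#'   analog).
#' @param folds outer fold count (default 10).
#' @param inner_folds inner fold count (default 5).
#' @param l1_ratio_grid elastic-net mixing grid (glmnet alpha; default
#'   \code{seq(0.1, 1, by = 0.1)}).
#' @param strength_grid regularization strengths (glmnet lambda; default 10
#'   points log-spaced over 1e-3..1e3).
#' @param seed integer seed controlling the fold splits.
#' @param family_name label stored on the report.
#' @return object of class \code{"enr_report"}: list with \code{family},
#'   \code{auc_mean}, \code{auc_sd}, \code{sens_mean}, \code{sens_sd},
#'   \code{spec_mean}, \code{spec_sd} (0-100 scale), \code{fold_metrics},
#'   \code{coefficients} (per-feature mean over outer folds, standardized
#'   scale), \code{chosen} (per-fold hyperparameters).
#' @export
nested_cv_enr <- function(x, y, folds = 10, inner_folds = 5,
                          l1_ratio_grid = seq(0.1, 1, by = 0.1),
                          strength_grid = 10^seq(-3, 3, length.out = 10),
                          seed = 0, family_name = "features") {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)), nrow(x) == length(y))
  strength_grid <- sort(strength_grid, decreasing = TRUE)
  # glmnet needs >= 2 columns; a lone feature is duplicated and its two
  # coefficients summed (identical predictions, same total coefficient)
  single <- ncol(x) == 1
  orig_names <- colnames(x)
  if (single) {
    x <- cbind(x, x)
    colnames(x) <- c(orig_names, paste0(orig_names, "__dup"))
  }
  with_seed(seed, {
    outer <- stratified_folds(y, folds)
    fold_metrics <- data.frame(fold = seq_len(folds), auc = NA_real_,
                               sens = NA_real_, spec = NA_real_)
    chosen <- data.frame(fold = seq_len(folds), l1_ratio = NA_real_,
                         lambda = NA_real_)
    coefs <- matrix(0, folds, ncol(x),
                    dimnames = list(NULL, colnames(x)))
    for (k in seq_len(folds)) {
      test <- outer == k
      if (length(unique(y[!test])) < 2 || length(unique(y[test])) < 2)
        stop("nested_cv_enr: stratification failure - a fold has one class")
      sc <- scale_train(x[!test, , drop = FALSE])
      xtr <- sc$x
      xte <- scale_apply(x[test, , drop = FALSE], sc)
      ytr <- y[!test]
      best <- inner_grid_search(xtr, ytr, inner_folds, l1_ratio_grid,
                                strength_grid)
      fit <- glmnet::glmnet(xtr, ytr, family = "binomial",
                            alpha = best$l1_ratio, lambda = strength_grid,
                            standardize = FALSE)
      prob <- as.numeric(stats::predict(fit, xte, s = best$lambda,
                                        type = "response", exact = FALSE))
      fold_metrics$auc[k] <- 100 * auc01(y[test], prob)
      pred <- as.integer(prob >= 0.5)
      # positive class = patient analog (label 0)
      fold_metrics$sens[k] <- 100 * mean(pred[y[test] == 0] == 0)
      fold_metrics$spec[k] <- 100 * mean(pred[y[test] == 1] == 1)
      chosen$l1_ratio[k] <- best$l1_ratio
      chosen$lambda[k] <- best$lambda
      cf <- as.matrix(stats::coef(fit, s = best$lambda))[-1, 1]
      coefs[k, names(cf)] <- cf
    }
    if (single)
      coefs <- matrix(rowSums(coefs), ncol = 1,
                      dimnames = list(NULL, orig_names))
    structure(list(family = family_name,
                   auc_mean = mean(fold_metrics$auc),
                   auc_sd = stats::sd(fold_metrics$auc),
                   sens_mean = mean(fold_metrics$sens),
                   sens_sd = stats::sd(fold_metrics$sens),
                   spec_mean = mean(fold_metrics$spec),
                   spec_sd = stats::sd(fold_metrics$spec),
                   fold_metrics = fold_metrics,
                   coefficients = colMeans(coefs),
                   chosen = chosen, seed = as.integer(seed)),
              class = "enr_report")
  })
}

#' @export
print.enr_report <- function(x, ...) {
  cat(sprintf("LR-ENR report [%s]\n", x$family))
  cat(sprintf("  AUC  %5.2f +/- %5.2f\n", x$auc_mean, x$auc_sd))
  cat(sprintf("  SENS %5.2f +/- %5.2f\n", x$sens_mean, x$sens_sd))
  cat(sprintf("  SPEC %5.2f +/- %5.2f\n", x$spec_mean, x$spec_sd))
  invisible(x)
}

#' Mean coefficient table from a fitted report
#'
#' Per-feature mean elastic-net coefficient across outer folds, on the
#' standardized feature scale. With label 1 = control analog, a negative
#' coefficient means higher feature values push toward the patient class.
#'
#' @param report an \code{\link{nested_cv_enr}} report.
#' @return data frame \code{feature}, \code{coefficient}, sorted by
#'   decreasing absolute value.
#' @export
coefficient_report <- function(report) {
  stopifnot(inherits(report, "enr_report"))
  out <- data.frame(feature = names(report$coefficients),
                    coefficient = unname(report$coefficients),
                    stringsAsFactors = FALSE)
  out[order(-abs(out$coefficient)), , drop = FALSE]
}

#' Run the classifier for every feature family
#'
#' @param features feature table with a \code{group} column (0 = control
#'   analog, 1 = patient analog); classification labels are remapped so that
#'   the patient analog is label 0 and the control analog label 1, matching
#'   the coefficient sign convention.
#' @param family_map named character vector feature -> family.
#' @param ... passed to \code{\link{nested_cv_enr}}.
#' @return named list of \code{enr_report}s, one per family.
#' @export
classify_families <- function(features, family_map = attr(features, "families"),
                              ...) {
  stopifnot(!is.null(family_map), "group" %in% colnames(features))
  y <- ifelse(features$group == 1, 0L, 1L)  # patient analog -> label 0
  fams <- unique(unname(family_map))
  out <- lapply(fams, function(fam) {
    cols <- names(family_map)[family_map == fam]
    cols <- cols[cols %in% colnames(features)]
    x <- as.matrix(features[, cols, drop = FALSE])
    nested_cv_enr(x, y, family_name = fam, ...)
  })
  stats::setNames(out, fams)
}

# --- internals -------------------------------------------------------------

# Stratified fold labels: each class dealt round-robin into folds in random
# order.
stratified_folds <- function(y, folds) {
  f <- integer(length(y))
  for (cls in unique(y)) {
    i <- which(y == cls)
    f[i[sample.int(length(i))]] <- rep_len(seq_len(folds), length(i))
  }
  f
}

# z-score with training statistics; zero-variance columns are dropped with a
# warning (they carry no information and would divide by zero).
scale_train <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  keep <- sd > 0
  if (!all(keep))
    warning("nested_cv_enr: zero-variance feature(s) excluded: ",
            paste(colnames(x)[!keep], collapse = ", "))
  if (sum(keep) == 0) stop("nested_cv_enr: no non-constant features")
  list(x = sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]), 2, sd[keep],
                 "/"),
       mu = mu, sd = sd, keep = keep)
}

scale_apply <- function(x, sc) {
  sweep(sweep(x[, sc$keep, drop = FALSE], 2, sc$mu[sc$keep]), 2,
        sc$sd[sc$keep], "/")
}

# Inner stratified grid search maximizing mean validation AUC.
inner_grid_search <- function(x, y, inner_folds, l1_ratio_grid,
                              strength_grid) {
  inner <- stratified_folds(y, inner_folds)
  score <- matrix(0, length(l1_ratio_grid), length(strength_grid))
  for (k in seq_len(inner_folds)) {
    val <- inner == k
    if (length(unique(y[val])) < 2 || length(unique(y[!val])) < 2) next
    for (a in seq_along(l1_ratio_grid)) {
      fit <- glmnet::glmnet(x[!val, , drop = FALSE], y[!val],
                            family = "binomial", alpha = l1_ratio_grid[a],
                            lambda = strength_grid, standardize = FALSE)
      prob <- stats::predict(fit, x[val, , drop = FALSE],
                             s = strength_grid, type = "response",
                             exact = FALSE)
      score[a, ] <- score[a, ] +
        apply(prob, 2, function(p) auc01(y[val], p))
    }
  }
  best <- which(score == max(score), arr.ind = TRUE)[1, ]
  list(l1_ratio = l1_ratio_grid[best[1]], lambda = strength_grid[best[2]])
}

# AUC in [0, 1] for predicting y == 1 from scores, via pROC.
auc01 <- function(y, score) {
  if (length(unique(y)) < 2) return(NA_real_)
  if (stats::var(score) == 0) return(0.5)
  as.numeric(pROC::auc(pROC::roc(response = y, predictor = score,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}
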