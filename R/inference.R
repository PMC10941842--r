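# Two-group inference on the feature table.
#
# Each feature gets a pooled-variance two-sample t-test (group 0 minus
# group 1, so a negative t means the patient analog scored higher);
# Benjamini-Hochberg FDR correction is applied within each feature family
# separately. Symptom-severity analysis regresses each feature on
# age + gender + site dummies + a symptom score within the patient group.

#' Pooled two-sample t-test
#'
#' Student's two-sample t with pooled variance, computed as group 0 minus
#' group 1, with a two-sided p-value.
#'
#' @param x0,x1 numeric samples (each of size >= 2).
#' @param var_equal pool the variances (default TRUE; set FALSE for Welch).
#' @return list with \code{t} and \code{p}.
#' @export
two_sample_ttest <- function(x0, x1, var_equal = TRUE) {
  stopifnot(length(x0) >= 2, length(x1) >= 2,
            all(is.finite(x0)), all(is.finite(x1)))
  if (stats::var(c(x0, x1)) == 0)
    stop("two_sample_ttest: degenerate (zero-variance) data")
  tt <- stats::t.test(x0, x1, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Benjamini-Hochberg step-up rejections
#'
#' Rejects all hypotheses with BH-adjusted p-value at or below \code{alpha},
#' equivalent to the step-up rule: reject \code{p_(i)} for all
#' \code{i <= max{i : p_(i) <= i * alpha / m}}.
#'
#' @param p_values p-values in \code{[0, 1]}.
#' @param alpha FDR level (default 0.05).
#' @return logical rejection flags, same order as the input.
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  stopifnot(all(p_values >= 0), all(p_values <= 1))
  stats::p.adjust(p_values, method = "BH") <= alpha
}

#' Per-family two-group tests with FDR control
#'
#' Runs the pooled t-test on every feature column of the table and applies
#' BH-FDR within each feature family separately. Rows are flagged both
#' uncorrected (\code{p <= alpha}) and FDR-corrected.
#'
#' @param features data frame from \code{\link{feature_table}} with a
#'   \code{group} column in \code{\{0, 1\}}.
#' @param family_map named character vector feature -> family; defaults to
#'   the map attached to \code{features}.
#' @param alpha significance / FDR level (default 0.05).
#' @param var_equal pooled (TRUE) or Welch (FALSE) t-test.
#' @return data frame: \code{feature}, \code{family}, \code{t}, \code{p},
#'   \code{significant_uncorrected}, \code{significant_fdr}.
#' @export
run_family_tests <- function(features, family_map = attr(features, "families"),
                             alpha = 0.05, var_equal = TRUE) {
  stopifnot(!is.null(family_map), "group" %in% colnames(features))
  cols <- names(family_map)[names(family_map) %in% colnames(features)]
  g <- features$group
  res <- lapply(cols, function(f) {
    tt <- two_sample_ttest(features[[f]][g == 0], features[[f]][g == 1],
                           var_equal = var_equal)
    data.frame(feature = f, family = unname(family_map[f]), t = tt$t,
               p = tt$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$significant_uncorrected <- res$p <= alpha
  res$significant_fdr <- FALSE
  for (fam in unique(res$family)) {
    i <- res$family == fam
    res$significant_fdr[i] <- bh_fdr(res$p[i], alpha)
  }
  res
}

#' Covariate-adjusted symptom-severity regression
#'
#' Within the group holding symptom scores (the patient analog), each
#' feature is regressed on age, gender, one-hot site (first level dropped)
#' and the symptom score:
#' \code{feature ~ age + gender + site + score}. The symptom coefficient,
#' its standard error and two-sided p-value are reported per feature, with
#' BH-FDR applied within each family.
#'
#' @param features feature table with covariate columns (\code{age},
#'   \code{gender}, \code{site}) and the symptom score column.
#' @param score_name symptom score column (default \code{"panss_neg"}).
#' @param family_map named character vector feature -> family.
#' @param alpha FDR level.
#' @return data frame: \code{feature}, \code{family}, \code{coefficient},
#'   \code{se}, \code{p}, \code{significant_uncorrected},
#'   \code{significant_fdr}.
#' @export
symptom_regression <- function(features, score_name = "panss_neg",
                               family_map = attr(features, "families"),
                               alpha = 0.05) {
  stopifnot(!is.null(family_map), score_name %in% colnames(features))
  dat <- features[!is.na(features[[score_name]]), , drop = FALSE]
  dat$site <- factor(dat$site)
  if (nlevels(dat$site) < 2) dat$site <- NULL
  cols <- names(family_map)[names(family_map) %in% colnames(dat)]
  rhs <- paste(c("age", "gender",
                 if (!is.null(dat$site)) "site", score_name),
               collapse = " + ")
  res <- lapply(cols, function(f) {
    fml <- stats::as.formula(paste0("`", f, "` ~ ", rhs))
    fit <- stats::lm(fml, data = dat)
    if (fit$rank < ncol(stats::model.matrix(fit)))
      stop("symptom_regression: rank-deficient design (collinearity)")
    co <- summary(fit)$coefficients
    data.frame(feature = f, family = unname(family_map[f]),
               coefficient = co[score_name, "Estimate"],
               se = co[score_name, "Std. Error"],
               p = co[score_name, "Pr(>|t|)"], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$significant_uncorrected <- res$p <= alpha
  res$significant_fdr <- FALSE
  for (fam in unique(res$family)) {
    i <- res$family == fam
    res$significant_fdr[i] <- bh_fdr(res$p[i], alpha)
  }
  res
}
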