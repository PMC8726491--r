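# Diagnostic-statistics layer: T-score classification, Mann-Whitney AUC with
# DeLong variance, Youden cutoffs, predictive values, paired DeLong tests,
# Spearman correlation with Fisher-z intervals, two-way mixed-effects
# absolute-agreement ICC, five-number summaries and group-difference tests.

# -- labels ------------------------------------------------------------------

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stopf("numeric labels must be 0/1")
    return(labels == 1)
  }
  labels <- as.character(labels)
  ok <- labels %in% c("osteoporosis", "non-osteoporosis")
  if (!all(ok)) stopf("labels must be logical, 0/1, or 'osteoporosis'/'non-osteoporosis'")
  labels == "osteoporosis"
}

#' Classify T-scores
#'
#' WHO densitometric classes with inclusive boundaries: osteoporosis
#' (T <= -2.5), osteopenia (-2.5 < T < -1.0), normal (T >= -1.0); the binary
#' regrouping labels T > -2.5 as non-osteoporosis.
#'
#' @param t Finite T-score(s).
#' @return A data.frame with `t_score`, `category` (three-level) and `group`
#'   (binary), both factors.
#' @export
classify_tscore <- function(t) {
  if (any(!is.finite(t))) stopf("T-scores must be finite")
  category <- ifelse(t <= -2.5, "osteoporosis",
                     ifelse(t >= -1.0, "normal", "osteopenia"))
  group <- ifelse(t <= -2.5, "osteoporosis", "non-osteoporosis")
  data.frame(
    t_score = t,
    category = factor(category, levels = c("osteoporosis", "osteopenia", "normal")),
    group = factor(group, levels = c("osteoporosis", "non-osteoporosis"))
  )
}

# -- ROC ---------------------------------------------------------------------

# Orient scores so larger = more diseased, and compute DeLong placement
# values. Ties contribute 1/2.
delong_placements <- function(scores, labels, direction) {
  labels <- as_binary_labels(labels)
  if (!any(labels) || all(labels)) stopf("both classes must be nonempty")
  x <- if (direction == "positive_if_low") -scores else scores
  pos <- x[labels]
  neg <- x[!labels]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  list(auc = mean(cmp), v10 = rowMeans(cmp), v01 = 1 - colMeans(cmp),
       n_pos = length(pos), n_neg = length(neg))
}

delong_var <- function(pl) {
  v10 <- if (pl$n_pos > 1) stats::var(pl$v10) else 0
  v01 <- if (pl$n_neg > 1) stats::var(1 - pl$v01) else 0
  v10 / pl$n_pos + v01 / pl$n_neg
}

#' Mann-Whitney AUC with DeLong confidence interval
#'
#' The AUC is the mean over all (positive, negative) pairs of the indicator
#' that the positive subject scores as more diseased (ties count 1/2), after
#' orienting by `direction`; the 95% CI uses the DeLong structural-component
#' variance and is truncated to \[0, 1\].
#'
#' @param scores Numeric index values.
#' @param labels Binary disease labels (logical, 0/1, or
#'   osteoporosis/non-osteoporosis strings).
#' @param direction `"positive_if_high"` (disease raises the index, e.g.
#'   HUHA fat fraction) or `"positive_if_low"` (mean HU, HUHA bone fraction).
#' @param conf_level Confidence level.
#' @return A list of class `roc_result`: `auc`, `ci95`, `se`, `direction`.
#' @export
auc_mann_whitney <- function(scores, labels,
                             direction = c("positive_if_high", "positive_if_low"),
                             conf_level = 0.95) {
  direction <- match.arg(direction)
  pl <- delong_placements(scores, labels, direction)
  se <- sqrt(delong_var(pl))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(1, pmax(0, pl$auc + c(-1, 1) * zq * se))
  structure(list(auc = pl$auc, ci95 = ci, se = se, direction = direction),
            class = "roc_result")
}

#' Youden-index optimal cutoff
#'
#' Scans thresholds at the observed score values and maximises
#' J = sensitivity + specificity - 1. The positivity rule is
#' `score <= cutoff` for `positive_if_low` indexes and `score > cutoff` for
#' `positive_if_high`, matching the reporting conventions "<= x HU" /
#' "> x %". Ties in J are broken toward higher sensitivity, then toward the
#' cutoff of smaller magnitude.
#'
#' @inheritParams auc_mann_whitney
#' @return A list: `cutoff`, `sens` and `spec` (percent), `j`.
#' @export
youden_cutoff <- function(scores, labels,
                          direction = c("positive_if_high", "positive_if_low")) {
  direction <- match.arg(direction)
  labels <- as_binary_labels(labels)
  if (!any(labels) || all(labels)) stopf("both classes must be nonempty")
  pos <- scores[labels]
  neg <- scores[!labels]
  cand <- sort(unique(scores))
  if (direction == "positive_if_low") {
    sens <- vapply(cand, function(c) mean(pos <= c), numeric(1))
    spec <- vapply(cand, function(c) mean(neg > c), numeric(1))
  } else {
    sens <- vapply(cand, function(c) mean(pos > c), numeric(1))
    spec <- vapply(cand, function(c) mean(neg <= c), numeric(1))
  }
  j <- sens + spec - 1
  ord <- order(-j, -sens, abs(cand))
  best <- ord[1]
  list(cutoff = cand[best], sens = 100 * sens[best], spec = 100 * spec[best],
       j = j[best])
}

#' Confusion matrix and predictive values from printed rates
#'
#' Reconstructs integer confusion counts from sensitivity/specificity
#' percentages and group sizes (rounding half away from zero), then derives
#' PPV and NPV. This is the arithmetic linking a published table's
#' sensitivity/specificity columns to its PPV/NPV columns at the study
#' prevalence.
#'
#' @param n_pos,n_neg Positive / negative group sizes (> 0).
#' @param sens,spec Sensitivity and specificity in percent.
#' @return A list: `tp`, `fp`, `fn`, `tn`, `ppv`, `npv` (percent).
#' @export
confusion_from_rates <- function(n_pos, n_neg, sens, spec) {
  if (n_pos <= 0 || n_neg <= 0) stopf("group sizes must be positive")
  if (sens < 0 || sens > 100 || spec < 0 || spec > 100) {
    stopf("`sens` and `spec` must be percentages in [0, 100]")
  }
  tp <- as.integer(round_half_up(sens * n_pos / 100))
  tn <- as.integer(round_half_up(spec * n_neg / 100))
  fn <- as.integer(n_pos) - tp
  fp <- as.integer(n_neg) - tn
  if (tp + fp == 0) stopf("PPV undefined: no test-positive subjects")
  if (tn + fn == 0) stopf("NPV undefined: no test-negative subjects")
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       ppv = 100 * tp / (tp + fp), npv = 100 * tn / (tn + fn))
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two indexes measured on the same subjects using the
#' covariance of their DeLong placement values; two-sided p from the normal
#' distribution. Identical (or rank-identical) score vectors give z = 0,
#' p = 1 with `degenerate = TRUE`.
#'
#' @param scores_a,scores_b Paired index values on identical subjects.
#' @param labels Binary labels.
#' @param direction_a,direction_b Orientation of each index.
#' @return A list: `auc_a`, `auc_b`, `z`, `p`, `degenerate`.
#' @export
delong_test <- function(scores_a, scores_b, labels,
                        direction_a = "positive_if_high",
                        direction_b = "positive_if_high") {
  if (length(scores_a) != length(scores_b)) {
    stopf("`scores_a` and `scores_b` must be paired (same subjects)")
  }
  pa <- delong_placements(scores_a, labels, direction_a)
  pb <- delong_placements(scores_b, labels, direction_b)
  var_a <- delong_var(pa)
  var_b <- delong_var(pb)
  cov_ab <- stats::cov(pa$v10, pb$v10) / pa$n_pos +
    stats::cov(1 - pa$v01, 1 - pb$v01) / pa$n_neg
  v <- var_a + var_b - 2 * cov_ab
  if (v <= 1e-16) {
    return(list(auc_a = pa$auc, auc_b = pb$auc, z = 0, p = 1,
                degenerate = TRUE))
  }
  z <- (pa$auc - pb$auc) / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z, p = 2 * stats::pnorm(-abs(z)),
       degenerate = FALSE)
}

# -- correlation and reliability --------------------------------------------

corr_category <- function(rho) {
  a <- abs(rho)
  if (a < 0.20) "negligible"
  else if (a < 0.40) "weak"
  else if (a < 0.60) "moderate"
  else if (a < 0.80) "strong"
  else "very strong"
}

#' Spearman correlation with Fisher-z confidence interval
#'
#' rho is the Pearson correlation of mid-ranks; the 95% CI uses the Fisher
#' z-transform with the variance-inflated standard error
#' sqrt((1 + rho^2 / 2) / (n - 3)). The magnitude is categorised as
#' negligible (< 0.20), weak, moderate, strong, or very strong (>= 0.80).
#'
#' @param x,y Numeric vectors, length >= 4, no missing values.
#' @return A list of class `corr_result`: `rho`, `ci95`, `n`, `category`.
#' @export
spearman_with_ci <- function(x, y) {
  if (length(x) != length(y)) stopf("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 4) stopf("need at least 4 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stopf("missing or non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stopf("constant input vector")
  rho <- stats::cor(rank(x), rank(y))
  se <- sqrt((1 + rho^2 / 2) / (n - 3))
  zr <- atanh(min(max(rho, -1 + 1e-15), 1 - 1e-15))
  ci <- tanh(zr + c(-1, 1) * stats::qnorm(0.975) * se)
  structure(list(rho = rho, ci95 = ci, n = n, category = corr_category(rho)),
            class = "corr_result")
}

icc_category <- function(icc) {
  if (icc < 0.50) "poor"
  else if (icc <= 0.75) "moderate"
  else if (icc <= 0.90) "good"
  else "excellent"
}

#' Two-way mixed-effects absolute-agreement ICC, single measure
#'
#' ICC(A,1) from the two-way ANOVA decomposition:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`, with the F-based
#' 95% confidence interval for single-measure absolute agreement
#' (Satterthwaite degrees of freedom for the denominator). Reliability is
#' categorised as poor (< 0.50), moderate (0.50-0.75), good (0.76-0.90) or
#' excellent (> 0.90).
#'
#' @param ratings n_subjects x k_raters numeric matrix, complete.
#' @return A list of class `icc_result`: `icc`, `ci95`, `category`, `n`, `k`.
#' @export
icc_two_way_mixed_absolute <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 2 || k < 2) stopf("need >= 2 subjects and >= 2 raters")
  if (any(!is.finite(ratings))) stopf("ratings table must be complete and finite")
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  grand <- mean(ratings)
  ss_total <- sum((ratings - grand)^2)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (abs(denom) < 1e-300 || ss_total == 0) {
    stopf("zero total variance: ICC undefined")
  }
  icc <- (msr - mse) / denom
  if (mse <= 0 && msc <= msr * 1e-12) {
    ci <- c(1, 1)
  } else {
    alpha <- 0.05
    icc_c <- min(icc, 1 - 1e-12)
    a <- k * icc_c / (n * (1 - icc_c))
    b <- 1 + k * icc_c * (n - 1) / (n * (1 - icc_c))
    v_num <- (a * msc + b * mse)^2
    v_den <- (a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1))
    v <- if (v_den > 0) v_num / v_den else Inf
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(max(-1, min(lower, 1)), max(-1, min(upper, 1)))
  }
  structure(list(icc = icc, ci95 = ci, category = icc_category(icc),
                 n = n, k = k),
            class = "icc_result")
}

# -- summaries ---------------------------------------------------------------

#' Five-number summary
#'
#' Minimum, first quartile, median, third quartile, maximum; quartiles use
#' the linear-interpolation convention (R quantile type 7).
#'
#' @param values Nonempty numeric vector.
#' @return Named numeric vector `(min, q1, median, q3, max)`.
#' @export
boxplot_summary <- function(values) {
  if (length(values) == 0L || any(!is.finite(values))) {
    stopf("`values` must be nonempty and finite")
  }
  q <- stats::quantile(values, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
  stats::setNames(q, c("min", "q1", "median", "q3", "max"))
}

#' Two-group difference test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test by default, optionally
#' Welch's t-test.
#'
#' @param values Numeric vector.
#' @param labels Binary group labels.
#' @param test `"mann_whitney"` (default) or `"t_test"`.
#' @return The two-sided p-value.
#' @export
group_difference_test <- function(values, labels,
                                  test = c("mann_whitney", "t_test")) {
  test <- match.arg(test)
  labels <- as_binary_labels(labels)
  if (!any(labels) || all(labels)) stopf("both groups must be nonempty")
  a <- values[labels]
  b <- values[!labels]
  if (test == "mann_whitney") {
    suppressWarnings(stats::wilcox.test(a, b)$p.value)
  } else {
    stats::t.test(a, b)$p.value
  }
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), %s\n", x$auc, x$ci95[1],
              x$ci95[2], x$direction))
  invisible(x)
}

#' @export
print.corr_result <- function(x, ...) {
  cat(sprintf("rho %.3f (95%% CI %.3f-%.3f), %s (n=%d)\n", x$rho, x$ci95[1],
              x$ci95[2], x$category, x$n))
  invisible(x)
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,1) %.3f (95%% CI %.3f-%.3f), %s (n=%d, k=%d)\n",
              x$icc, x$ci95[1], x$ci95[2], x$category, x$n, x$k))
  invisible(x)
}
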