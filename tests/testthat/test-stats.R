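# Statistical layer: AUC/DeLong, Youden, predictive values, Spearman, ICC,
# summaries. Oracles: pair enumeration, trapezoid ROC area, aov() mean
# squares, pROC, exhaustive permutation.

test_that("AUC equals the pairwise enumeration on the worked example", {
  scores <- c(2, 3, 1, 2)
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  r <- auc_mann_whitney(scores, labels, direction = "positive_if_high")
  expect_equal(r$auc, 0.875)  # pairs: 1, .5, 1, 1
  expect_equal(auc_mann_whitney(c(5, 6, 1, 2), labels)$auc, 1)
  expect_equal(auc_mann_whitney(rep(3, 4), labels)$auc, 0.5)
  expect_error(auc_mann_whitney(1:3, c(TRUE, TRUE, TRUE)), "nonempty")
})

test_that("AUC equals the trapezoidal ROC area and is rank-invariant", {
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(10:40, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.4)
    scores <- round(rnorm(n, ifelse(labels, 1, 0)), 1)  # with ties
    dir <- sample(c("positive_if_high", "positive_if_low"), 1)
    a <- auc_mann_whitney(scores, labels, direction = dir)$auc
    expect_equal(a, trapezoid_auc(scores, labels, dir), tolerance = 1e-12)
    # strictly monotone transform leaves the AUC unchanged
    a2 <- auc_mann_whitney(exp(scores / 2), labels, direction = dir)$auc
    expect_equal(a, a2, tolerance = 1e-12)
  }
})

test_that("DeLong AUC confidence intervals agree with pROC", {
  set.seed(9)
  labels <- runif(60) < 0.35
  labels[1:2] <- c(TRUE, FALSE)
  scores <- rnorm(60, ifelse(labels, 1.2, 0))
  r <- auc_mann_whitney(scores, labels)
  pr <- pROC::roc(response = labels, predictor = scores,
                  direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(r$ci95, ci[c(1, 3)], tolerance = 1e-9)
})

test_that("Youden cutoffs follow the per-direction positivity conventions", {
  y <- youden_cutoff(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE),
                     direction = "positive_if_low")
  expect_equal(y$cutoff, 2)
  expect_equal(y$sens, 100)
  expect_equal(y$spec, 100)
  y2 <- youden_cutoff(c(5, 1), c(TRUE, FALSE), direction = "positive_if_high")
  expect_equal(y2$cutoff, 1)
  expect_equal(y2$j, 1)
  # identical score multisets: J = 0 everywhere, deterministic tie-break
  y3a <- youden_cutoff(c(1, 2, 1, 2), c(TRUE, TRUE, FALSE, FALSE),
                       direction = "positive_if_low")
  y3b <- youden_cutoff(c(2, 1, 2, 1), c(FALSE, TRUE, TRUE, FALSE),
                       direction = "positive_if_low")
  expect_equal(y3a$j, 0)
  expect_identical(y3a, y3b)
  expect_equal(y3a$sens, 100)  # tie toward higher sensitivity
})

test_that("Youden cutoff maximises J against an exhaustive scan", {
  set.seed(10)
  for (rep in 1:15) {
    n <- 30
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.4)
    scores <- round(rnorm(n, ifelse(labels, -0.8, 0.4)), 1)
    y <- youden_cutoff(scores, labels, direction = "positive_if_low")
    js <- vapply(sort(unique(scores)), function(c) {
      mean(scores[labels] <= c) + mean(scores[!labels] > c) - 1
    }, numeric(1))
    expect_equal(y$j, max(js), tolerance = 1e-12)
  }
})

test_that("predictive values reconstructed from printed rates", {
  r3d <- confusion_from_rates(96, 334, 94.8, 85.0)
  expect_equal(round(r3d$ppv, 1), 64.5)
  expect_equal(round(r3d$npv, 1), 98.3)
  r2d <- confusion_from_rates(96, 334, 89.6, 87.4)
  expect_equal(round(r2d$ppv, 1), 67.2)
  expect_equal(round(r2d$npv, 1), 96.7)
  perfect <- confusion_from_rates(10, 10, 100, 100)
  expect_equal(perfect$ppv, 100)
  expect_equal(perfect$npv, 100)
  expect_error(confusion_from_rates(10, 10, 0, 100), "undefined")
})

test_that("confusion matrices round-trip through rates", {
  set.seed(11)
  for (rep in 1:20) {
    n_pos <- sample(5:200, 1); n_neg <- sample(5:400, 1)
    tp <- sample(0:n_pos, 1); tn <- sample(0:n_neg, 1)
    if (tp + (n_neg - tn) == 0 || tn + (n_pos - tp) == 0) next
    r <- confusion_from_rates(n_pos, n_neg, 100 * tp / n_pos, 100 * tn / n_neg)
    expect_identical(c(r$tp, r$tn), c(tp, tn))
  }
})

test_that("DeLong paired test: degeneracy, rank invariance, oracle variance", {
  labels <- c(rep(TRUE, 5), rep(FALSE, 5))
  set.seed(12)
  a <- rnorm(10, ifelse(labels, 1, 0))
  same <- delong_test(a, a, labels)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)
  # monotone transform of the same index: AUC is rank-invariant
  mono <- delong_test(a, 3 * a + 2, labels)
  expect_equal(mono$p, 1)
  # variance components equal the brute-force placement covariance
  b <- rnorm(10, ifelse(labels, 0.5, 0))
  dt <- delong_test(a, b, labels)
  pa <- femhu:::delong_placements(a, labels, "positive_if_high")
  pb <- femhu:::delong_placements(b, labels, "positive_if_high")
  v <- var(pa$v10) / 5 + var(1 - pa$v01) / 5 +
    var(pb$v10) / 5 + var(1 - pb$v01) / 5 -
    2 * (cov(pa$v10, pb$v10) / 5 + cov(1 - pa$v01, 1 - pb$v01) / 5)
  expect_equal(dt$z, (pa$auc - pb$auc) / sqrt(v), tolerance = 1e-12)
  # and the two-sided p agrees with pROC on a larger fixture
  labels2 <- runif(80) < 0.4; labels2[1:2] <- c(TRUE, FALSE)
  s1 <- rnorm(80, ifelse(labels2, 1, 0)); s2 <- rnorm(80, ifelse(labels2, .7, 0))
  ours <- delong_test(s1, s2, labels2)
  r1 <- pROC::roc(labels2, s1, direction = "<", quiet = TRUE)
  r2 <- pROC::roc(labels2, s2, direction = "<", quiet = TRUE)
  pr <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
  expect_equal(ours$p, as.numeric(pr$p.value), tolerance = 1e-9)
})

test_that("Spearman rho, CI and categories", {
  expect_equal(spearman_with_ci(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_with_ci(1:10, -(1:10))$rho, -1)
  r <- spearman_with_ci(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$rho, 0.8)
  expect_equal(r$category, "very strong")
  set.seed(13)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  expect_equal(spearman_with_ci(x, y)$rho,
               cor(x, y, method = "spearman"), tolerance = 1e-12)
  expect_error(spearman_with_ci(rep(1, 6), 1:6), "constant")
  expect_error(spearman_with_ci(1:3, 1:3), "at least 4")
  expect_equal(femhu:::corr_category(0.1), "negligible")
  expect_equal(femhu:::corr_category(-0.3), "weak")
  expect_equal(femhu:::corr_category(0.45), "moderate")
  expect_equal(femhu:::corr_category(0.7), "strong")
})

test_that("ICC(A,1) matches hand arithmetic and the ANOVA oracle", {
  # identical rater columns: perfect agreement
  tab <- cbind(c(1, 5, 9, 13), c(1, 5, 9, 13))
  r <- icc_two_way_mixed_absolute(tab)
  expect_equal(r$icc, 1)
  expect_equal(r$category, "excellent")
  # hand-computed 3x2 table: MSR = 8, MSC = 1.5, MSE = 0 -> ICC = 8/9
  r2 <- icc_two_way_mixed_absolute(rbind(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(r2$icc, 8 / 9, tolerance = 1e-12)
  # constant offset between raters is penalised (absolute agreement) and
  # matches the aov() oracle
  tab3 <- cbind(c(2, 4, 9, 12, 20), c(2, 4, 9, 12, 20) + 3)
  r3 <- icc_two_way_mixed_absolute(tab3)
  expect_lt(r3$icc, 1)
  expect_equal(r3$icc, icc_a1_oracle(tab3), tolerance = 1e-10)
  expect_error(icc_two_way_mixed_absolute(matrix(5, 4, 2)), "zero total variance")
  expect_error(icc_two_way_mixed_absolute(cbind(1:3, c(1, NA, 3))), "complete")
})

test_that("ICC equals the brute-force ANOVA oracle on random tables", {
  set.seed(14)
  for (rep in 1:100) {
    n <- sample(4:12, 1); k <- sample(2:4, 1)
    subj <- rnorm(n, 0, sample(c(0.5, 1, 2), 1))
    tab <- outer(subj, rnorm(k, 0, 0.5), "+") + matrix(rnorm(n * k, 0, 0.7), n, k)
    expect_equal(icc_two_way_mixed_absolute(tab)$icc, icc_a1_oracle(tab),
                 tolerance = 1e-10)
  }
  expect_equal(femhu:::icc_category(0.3), "poor")
  expect_equal(femhu:::icc_category(0.6), "moderate")
  expect_equal(femhu:::icc_category(0.85), "good")
  expect_equal(femhu:::icc_category(0.95), "excellent")
})

test_that("five-number summary follows the linear-interpolation convention", {
  expect_equal(unname(boxplot_summary(1:5)), c(1, 2, 3, 4, 5))
  expect_equal(unname(boxplot_summary(7)), rep(7, 5))
  set.seed(15)
  v <- rnorm(37)
  expect_equal(boxplot_summary(v), boxplot_summary(sample(v)))
  expect_error(boxplot_summary(numeric(0)), "nonempty")
})

test_that("group difference test agrees with exact enumeration at small n", {
  expect_gt(group_difference_test(c(1:5, 1:5), rep(c(TRUE, FALSE), each = 5)),
            0.99)
  expect_lt(group_difference_test(c(rnorm(60), rnorm(60) + 10),
                                  rep(c(TRUE, FALSE), each = 60)), 0.001)
  set.seed(16)
  for (rep in 1:10) {
    a <- rnorm(3); b <- rnorm(3) + 0.5   # continuous draws: no ties
    p <- group_difference_test(c(a, b), rep(c(TRUE, FALSE), each = 3))
    expect_equal(p, mann_whitney_enum_p(a, b), tolerance = 1e-12)
  }
})
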