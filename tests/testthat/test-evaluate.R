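test_that("metrics reproduce the closed-form confusion-matrix example", {
  ## 19/21 split with TP = 18, FN = 1, TN = 18, FP = 3
  y <- rep(c(1L, 2L), c(19L, 21L))
  pred <- c(rep(1L, 18), 2L, rep(1L, 3), rep(2L, 18))
  m <- compute_metrics(pred, NULL, y)
  expect_equal(m$sensitivity, 18 / 19)
  expect_equal(m$specificity, 18 / 21)
  expect_equal(m$weighted_accuracy, (18 / 19 + 18 / 21) / 2)
  expect_equal(m$f1, 2 * (18 / 21) * (18 / 19) / (18 / 21 + 18 / 19))
  expect_true("auc_omitted" %in% m$flags)
})

test_that("perfect and trivial predictors hit the metric boundaries", {
  y <- rep(c(1L, 2L), each = 10)
  m <- compute_metrics(y, c(rep(1, 10), rep(-1, 10)), y)
  expect_equal(m$weighted_accuracy, 1)
  expect_equal(m$f1, 1)
  expect_equal(m$auc, 1)
  ## all-one-class predictions: weighted accuracy 0.5
  m2 <- compute_metrics(rep(1L, 20), NULL, y)
  expect_equal(m2$weighted_accuracy, 0.5)
})

test_that("AUC equals the rank statistic on pooled decision values", {
  set.seed(3)
  y <- rep(c(1L, 2L), each = 25)
  dec <- ifelse(y == 1L, 0.8, -0.4) + rnorm(50)
  m <- compute_metrics(ifelse(dec > 0, 1L, 2L), dec, y)
  wilcox_auc <- mean(outer(dec[y == 1L], dec[y == 2L], `>`) +
                       0.5 * outer(dec[y == 1L], dec[y == 2L], `==`))
  expect_equal(m$auc, wilcox_auc, tolerance = 1e-12)
})

test_that("a separable planted feature yields a one-feature optimum at accuracy 1", {
  tab <- separable_table(5, n = 20)[, c(1:2, 2 + 1:60)]
  class(tab) <- c("delta_table", "data.frame")
  res <- loocv_subset_search(tab, s_max = 10)
  expect_equal(res$optimal_size, 1L)
  expect_equal(res$report$weighted_accuracy, 1)
  expect_equal(res$optimal_subset, feature_registry()$id[5])
  expect_length(res$fold_rankings, nrow(tab))
})

test_that("LOOCV honesty: perturbing a held-out row leaves its fold's ranking unchanged", {
  tab <- null_table(17, n = 12, p = 16)
  res <- loocv_subset_search(tab, s_max = 5)
  tab2 <- tab
  tab2[3, -(1:2)] <- tab2[3, -(1:2)] + 100  # poison row 3
  res2 <- loocv_subset_search(tab2, s_max = 5)
  ## fold 3 trains without row 3: identical artifacts
  expect_identical(res$fold_rankings[[3]], res2$fold_rankings[[3]])
  ## other folds see the poisoned row and must differ somewhere
  expect_false(identical(res$fold_rankings[[1]], res2$fold_rankings[[1]]))
})

test_that("permutation test is significant on a separable fixture", {
  tab <- separable_table(7)
  res <- loocv_subset_search(tab, s_max = 5)
  pt <- permutation_test(tab, subset = res$optimal_subset, n_perm = 100,
                         seed = 11)
  expect_equal(pt$observed, 1)
  expect_lte(pt$p_value, 0.01)
  ## strict mode can only lower the count
  pt2 <- permutation_test(tab, subset = res$optimal_subset, n_perm = 100,
                          seed = 11, strict = TRUE)
  expect_lte(pt2$p_value, pt$p_value)
})

test_that("permutation p is calibrated for a label-independent subset", {
  ## under the null, with the evaluated subset fixed a priori, p is uniform
  pvals <- vapply(1:30, function(s) {
    tab <- null_table(300 + s, n = 14, p = 10)
    permutation_test(tab, subset = names(tab)[3:6], n_perm = 40,
                     seed = s)$p_value
  }, numeric(1))
  ## p is discrete (multiples of 1/n_perm), hence the tie suppression
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
  expect_gt(mean(pvals), 0.3)
})

test_that("weekly stability reports per-week metrics and flags missing weeks", {
  tabs <- list("2" = separable_table(8), "3" = separable_table(9))
  out <- weekly_stability(tabs, subset = feature_registry()$id[5])
  expect_equal(out$cbct, c(2L, 3L))
  expect_equal(out$week, c(1L, 2L))
  expect_true(all(out$weighted_accuracy == 1))
  expect_equal(attr(out, "missing_weeks"), c(4L, 5L))
})

test_that("weekly accuracy decays on a cohort whose effect fades", {
  ## plant a margin that shrinks with week
  mk <- function(margin, seed) separable_table(seed, margin = margin)
  tabs <- list("2" = mk(5, 21), "3" = mk(1.0, 22), "4" = mk(0.4, 23),
               "5" = mk(0.1, 24))
  out <- weekly_stability(tabs, subset = feature_registry()$id[5])
  expect_true(all(diff(out$weighted_accuracy) <= 0.05))
  expect_lt(out$weighted_accuracy[4], out$weighted_accuracy[1])
})

test_that("two-group ANOVA agrees with the squared-t identity and finds planted shifts", {
  set.seed(31)
  n <- 30
  y <- rep(c(1L, 2L), each = n / 2)
  x <- rnorm(n) + ifelse(y == 1L, 1, 0)
  tab <- data.frame(label = y, f1 = x, f2 = rnorm(n))
  res <- per_feature_anova(tab)
  tt <- t.test(x ~ factor(y), var.equal = TRUE)
  expect_equal(res$F[1], unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p[1], tt$p.value, tolerance = 1e-10)
  ## identical class distributions: p far from significant on average
  expect_gt(res$p[2], 0.05)
})

test_that("planted 2-SD shifts are detected by ANOVA in nearly all runs", {
  hits <- vapply(1:100, function(s) {
    set.seed(s + 1000)
    y <- rep(c(1L, 2L), c(19, 21))
    x <- rnorm(40) + ifelse(y == 1L, 2, 0)
    tab <- data.frame(label = y, f = x)
    per_feature_anova(tab)$p[1] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("feature-volume correlation behaves as Pearson r", {
  set.seed(41)
  n <- 40
  vol <- data.frame(CTV = rnorm(n), PG = rnorm(n))
  tab <- data.frame(label = rep(c(1L, 2L), each = n / 2),
                    fa = vol$CTV, fb = rnorm(n), fc = rep(1, n))
  res <- feature_volume_correlation(tab, vol)
  r_aa <- res$r[res$feature == "fa" & res$roi_volume == "CTV"]
  expect_equal(r_aa, 1, tolerance = 1e-12)
  ## antisymmetry: negating a column negates r
  tab2 <- tab; tab2$fa <- -tab2$fa
  res2 <- feature_volume_correlation(tab2, vol)
  expect_equal(res2$r[res2$feature == "fa" & res2$roi_volume == "CTV"],
               -r_aa)
  ## constant column flagged NA
  expect_true(is.na(res$r[res$feature == "fc" & res$roi_volume == "CTV"]))
  ## null sampling: |r| below the n = 40 critical band in ~95 % of draws
  rs <- vapply(1:200, function(s) {
    set.seed(s)
    cor(rnorm(40), rnorm(40))
  }, numeric(1))
  expect_gt(mean(abs(rs) < 0.32), 0.9)
})

test_that("comparison classifiers run behind the common interface", {
  tab <- separable_table(55, n = 20)
  for (mth in c("svm_linear", "svm_gaussian", "knn", "lda")) {
    m <- loocv_classifier(tab, feature_registry()$id[5], method = mth)
    expect_s3_class(m, "eval_report")
    expect_gte(m$weighted_accuracy, 0.9)
  }
})
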