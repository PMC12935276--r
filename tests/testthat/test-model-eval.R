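test_that("protocol cardinality multiplies repeats by folds", {
  expect_equal(evaluation_fold_count(cv_protocol(50, 5)), 250)
  expect_equal(evaluation_fold_count(cv_protocol(1, 5)), 5)
  expect_equal(evaluation_fold_count(cv_protocol(10, 3)), 30)
})

test_that("MCC follows its formula with the degenerate-denominator convention", {
  expect_equal(mcc(3, 3, 1, 1), 0.5)
  expect_equal(mcc(10, 10, 0, 0), 1)       # perfect prediction
  expect_equal(mcc(0, 0, 10, 10), -1)      # perfectly wrong
  expect_equal(mcc(5, 0, 5, 0), 0)         # all predictions one class
  expect_equal(mcc(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)), 0.5)
  expect_error(mcc(-1, 2, 3, 4), "non-negative")
})

test_that("MCC is invariant under a joint class swap and negates on prediction flip", {
  # joint swap: (TP,TN,FP,FN) -> (TN,TP,FN,FP)
  expect_equal(mcc(7, 2, 4, 1), mcc(2, 7, 1, 4))
  # flipping only the predictions: (TP,TN,FP,FN) -> (FN,FP,TN,TP)
  expect_equal(mcc(6, 6, 2, 2), -mcc(2, 2, 6, 6))
})

test_that("metric summaries use the mean +/- 1.96 sd / sqrt(n) convention", {
  ci <- metric_ci(0.8061, 0.0340, 250)
  expect_equal(round(ci$ci_low, 4), 0.8019)
  expect_equal(round(ci$ci_high, 4), 0.8103)
  ci2 <- metric_ci(0.5, 0.1, 100)
  expect_equal(c(ci2$ci_low, ci2$ci_high), c(0.4804, 0.5196))
  s <- summarize_metrics(data.frame(accuracy = c(0.7, 0.7, 0.7)))
  expect_equal(s$sd, 0)
  expect_equal(s$ci_low, s$ci_high)
})

test_that("Welch comparison matches stats::t.test and the textbook formulas", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  w <- welch_compare(a, b)
  tt <- t.test(a, b)
  expect_equal(w$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(tt$parameter), tolerance = 1e-12)
  expect_equal(w$p_value, tt$p.value, tolerance = 1e-12)
  # frozen hand evaluation: t = -1/sqrt(5/6), df = 6, g = -(1/sqrt(5/3))*20/23
  expect_equal(w$t, -1.095445115010332, tolerance = 1e-10)
  expect_equal(w$df, 6, tolerance = 1e-10)
  expect_equal(w$hedges_g, -0.673562321079551, tolerance = 1e-10)

  # identical samples: no difference
  w0 <- welch_compare(a, a)
  expect_equal(w0$t, 0)
  expect_equal(w0$p_value, 1)
  expect_equal(w0$hedges_g, 0)

  # equal-variance equal-n samples approach pooled df = n1 + n2 - 2
  set.seed(5)
  x <- rnorm(250); y <- x + 0.1          # identical variances by construction
  expect_lt(abs(welch_compare(x, y)$df - 498), 1)

  expect_error(welch_compare(rep(1, 5), rep(2, 5)), "zero variance")
  expect_error(welch_compare(1, 1:3), "at least 2")

  set.seed(6)
  x <- rnorm(30); y <- rnorm(40, 0.5, 2)
  w2 <- welch_compare(x, y)
  tt2 <- t.test(x, y)
  expect_equal(w2$t, unname(tt2$statistic), tolerance = 1e-12)
  expect_equal(w2$df, unname(tt2$parameter), tolerance = 1e-12)
})

test_that("p-value adjustment reproduces the hand-computed corrections", {
  raw <- c(0.005, 0.01, 0.03, 0.04, 0.2)
  expect_equal(adjust_pvalues(raw, "bonferroni"),
               c(0.025, 0.05, 0.15, 0.2, 1.0))
  expect_equal(adjust_pvalues(raw, "holm"),
               c(0.025, 0.04, 0.09, 0.09, 0.2))
  expect_equal(adjust_pvalues(0.03, "bonferroni"), 0.03)
  expect_equal(adjust_pvalues(0.03, "holm"), 0.03)
  expect_error(adjust_pvalues(c(0.5, 1.2), "holm"), "0, 1")
  # order of outputs follows order of inputs
  shuf <- c(0.2, 0.005, 0.04, 0.01, 0.03)
  expect_equal(adjust_pvalues(shuf, "holm"),
               c(0.2, 0.025, 0.09, 0.04, 0.09))
})

test_that("Holm never exceeds Bonferroni on random p-vectors", {
  set.seed(8)
  for (i in 1:200) {
    p <- runif(5)
    expect_true(all(adjust_pvalues(p, "holm") <=
                      adjust_pvalues(p, "bonferroni") + 1e-15))
  }
})

test_that("repeated CV is deterministic and near-perfect on separable features", {
  f <- separable_features(n = 400, margin = 2.5)
  proto <- cv_protocol(n_repeats = 2, n_folds = 3)
  cv1 <- repeated_cv_evaluate(f, proto)
  cv2 <- repeated_cv_evaluate(f, proto)
  expect_identical(cv1$metrics, cv2$metrics)
  expect_identical(cv1$importance, cv2$importance)
  expect_equal(nrow(cv1$metrics), 6)
  expect_gte(mean(cv1$metrics$accuracy), 0.95)
  expect_gte(mean(cv1$metrics$mcc), 0.9)
  # every importance vector is normalized
  expect_equal(unname(rowSums(cv1$importance)), rep(1, 6), tolerance = 1e-9)
})

test_that("metric values stay in range and summaries carry all five metrics", {
  f <- separable_features(n = 120, margin = 0.2, seed = 9)
  cv <- repeated_cv_evaluate(f, cv_protocol(2, 3))
  m <- cv$metrics
  expect_true(all(m$accuracy >= 0 & m$accuracy <= 1))
  expect_true(all(m$mcc >= -1 & m$mcc <= 1))
  s <- summarize_metrics(cv)
  expect_setequal(s$metric, c("accuracy", "precision", "recall", "f1", "mcc"))
  expect_true(all(s$ci_low <= s$mean & s$mean <= s$ci_high))
})

test_that("planted early-interval signal dominates the feature importances", {
  set.seed(12)
  n <- 300
  x <- matrix(rnorm(n * 10), ncol = 10,
              dimnames = list(NULL, paste0("dH_t", 1:10)))
  y <- as.integer(x[, 1] + x[, 2] + x[, 3] > 0)
  f <- data.frame(x, result = y)
  cv <- repeated_cv_evaluate(f, cv_protocol(2, 3))
  imp <- feature_importance_summary(cv)
  top3 <- imp$feature[order(-imp$mean_importance)][1:3]
  expect_setequal(top3, c("dH_t1", "dH_t2", "dH_t3"))
})

test_that("alpha comparison table carries Welch results and ordered corrections", {
  f1 <- separable_features(n = 150, margin = 1.2, seed = 1)
  f2 <- f1
  set.seed(2); f2$result <- sample(f2$result)   # destroy the signal
  cv_good <- repeated_cv_evaluate(f1, cv_protocol(2, 3))
  cv_null <- repeated_cv_evaluate(f2, cv_protocol(2, 3))
  cmp <- compare_alphas(list("0" = cv_good, "1" = cv_null), baseline = "1")
  expect_equal(nrow(cmp), 1)
  expect_gt(cmp$mean_diff, 0)
  expect_gt(cmp$hedges_g, 0)
  expect_true(all(cmp$p_holm <= cmp$p_bonferroni + 1e-15))
  w <- welch_compare(cv_good$metrics$mcc, cv_null$metrics$mcc)
  expect_equal(cmp$t, w$t)
  expect_equal(cmp$df, w$df)
})
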