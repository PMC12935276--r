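#' Repeated cross-validation protocol
#'
#' Describes the model-comparison protocol: `n_repeats` rounds of shuffled
#' `n_folds`-fold cross-validation (250 held-out evaluations at the
#' defaults), where each repetition shuffles with its own seed equal to the
#' repetition index, hyperparameters are tuned by grid search *inside* the
#' training folds of every evaluation (inner CV scored by accuracy), and the
#' random-forest model seed is fixed at 42.
#'
#' @param n_repeats number of shuffled repetitions (default 50).
#' @param n_folds outer folds per repetition (default 5).
#' @param inner_folds folds of the inner tuning CV (default 5).
#' @param model_seed forest seed used for every fit (default 42).
#' @param stratified use class-stratified outer folds? Default `FALSE`
#'   (plain shuffled folds).
#' @return a `cv_protocol` object.
#' @export
cv_protocol <- function(n_repeats = 50L, n_folds = 5L, inner_folds = 5L,
                        model_seed = 42L, stratified = FALSE) {
  stopifnot(n_repeats >= 1, n_folds >= 2, inner_folds >= 2)
  structure(list(n_repeats = as.integer(n_repeats),
                 n_folds = as.integer(n_folds),
                 inner_folds = as.integer(inner_folds),
                 model_seed = as.integer(model_seed),
                 stratified = isTRUE(stratified)),
            class = "cv_protocol")
}

#' Number of held-out evaluations a protocol produces
#'
#' @param protocol a [cv_protocol()].
#' @return `n_repeats * n_folds`.
#' @examples
#' evaluation_fold_count(cv_protocol(50, 5))  # 250
#' @export
evaluation_fold_count <- function(protocol) {
  stopifnot(inherits(protocol, "cv_protocol"))
  protocol$n_repeats * protocol$n_folds
}

#' Random-forest hyperparameter grid
#'
#' The full grid spans `n_estimators` (number of trees), `max_depth` (`NA`
#' means unlimited), `min_samples_split`, `min_samples_leaf` and `bootstrap`
#' (with/without resampling). The `reduced` grid keeps trees at 100 and only
#' varies depth, which preserves the tuning machinery at a fraction of the
#' cost and is the default for simulation-scale runs.
#'
#' @param grid_mode `"reduced"` or `"full"`.
#' @return data.frame with one row per hyperparameter configuration.
#' @export
rf_grid <- function(grid_mode = c("reduced", "full")) {
  grid_mode <- match.arg(grid_mode)
  if (grid_mode == "full")
    expand.grid(n_estimators = c(50, 100, 200),
                max_depth = c(NA, 10, 20, 30),
                min_samples_split = c(2, 5, 10),
                min_samples_leaf = c(1, 2, 4),
                bootstrap = c(TRUE, FALSE),
                KEEP.OUT.ATTRS = FALSE)
  else
    expand.grid(n_estimators = 100,
                max_depth = c(NA, 10),
                min_samples_split = 2,
                min_samples_leaf = 1,
                bootstrap = TRUE,
                KEEP.OUT.ATTRS = FALSE)
}

fit_rf <- function(x, y, cfg, seed) {
  ranger::ranger(x = x, y = y,
                 num.trees = cfg$n_estimators,
                 max.depth = if (is.na(cfg$max_depth)) 0 else cfg$max_depth,
                 min.node.size = cfg$min_samples_split,
                 min.bucket = cfg$min_samples_leaf,
                 replace = cfg$bootstrap,
                 sample.fraction = 1,
                 importance = "impurity",
                 seed = seed, num.threads = 1)
}

predict_rf <- function(fit, x) {
  stats::predict(fit, data = x, num.threads = 1)$predictions
}

#' Matthews correlation coefficient from a 2x2 confusion
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the usual
#' convention that a zero denominator (a degenerate row or column, e.g. all
#' predictions in one class) yields 0.
#'
#' @param tp,tn,fp,fn confusion counts; alternatively pass a 2x2 matrix as
#'   `tp` with layout `rbind(c(TP, FN), c(FP, TN))`.
#' @return a value in `[-1, 1]`.
#' @examples
#' mcc(3, 3, 1, 1)  # 0.5
#' @export
mcc <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.matrix(tp)) {
    stopifnot(all(dim(tp) == 2))
    fn <- tp[1, 2]; fp <- tp[2, 1]; tn <- tp[2, 2]; tp <- tp[1, 1]
  }
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  denom <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) * sqrt((tn + fn))
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / denom
}

classification_metrics <- function(truth, pred) {
  tp <- sum(pred == 1 & truth == 1); tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0); fn <- sum(pred == 0 & truth == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  c(accuracy = (tp + tn) / length(truth), precision = precision,
    recall = recall, f1 = f1, mcc = mcc(tp, tn, fp, fn))
}

make_folds <- function(n, k, seed, y = NULL, stratified = FALSE) {
  set.seed(seed)
  idx <- sample.int(n)
  fold <- integer(n)
  if (stratified && !is.null(y)) {
    for (cl in unique(y[idx])) {
      ii <- idx[y[idx] == cl]
      fold[ii] <- rep_len(seq_len(k), length(ii))
    }
  } else {
    fold[idx] <- cut(seq_len(n), breaks = k, labels = FALSE)
  }
  fold
}

inner_grid_search <- function(x, y, grid, inner_folds, model_seed, seed) {
  if (nrow(grid) == 1) return(1L)
  fold <- make_folds(nrow(x), inner_folds, seed = seed)
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    mean(vapply(seq_len(inner_folds), function(f) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2) return(NA_real_)
      fit <- fit_rf(x[tr, , drop = FALSE], y[tr], grid[g, ], model_seed)
      mean(predict_rf(fit, x[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  which.max(acc)  # ties: first configuration in grid order
}

#' Repeated cross-validated random-forest evaluation
#'
#' The model-comparison workhorse: for each repetition `r` the rows are
#' shuffled with seed `r` and split into `n_folds` folds; for each fold, a
#' grid search tuned by inner cross-validation on the training folds alone
#' picks the forest hyperparameters (scored by accuracy), the chosen
#' configuration is refit on the full training folds with the fixed model
#' seed, and the held-out fold is scored on accuracy, precision, recall, F1
#' and MCC (positive class: Team A win). The run is bit-deterministic given
#' the data and protocol. Folds whose training data contain a single class
#' are skipped with a warning and recorded as missing.
#'
#' @param features an `edran_features` table (columns `dH_t1`..`dH_t10` and
#'   `result`), or any data.frame of numeric features plus a 0/1 `result`.
#' @param protocol a [cv_protocol()].
#' @param grid_mode hyperparameter grid, see [rf_grid()].
#' @return an `edran_cv` object: `metrics` (one row per evaluation),
#'   `importance` (evaluations x features matrix of impurity importances,
#'   each row normalized to sum 1), `protocol`, `grid_mode` and the feature
#'   `alpha` if known.
#' @export
repeated_cv_evaluate <- function(features, protocol = cv_protocol(),
                                 grid_mode = c("reduced", "full")) {
  grid_mode <- match.arg(grid_mode)
  grid <- rf_grid(grid_mode)
  cols <- setdiff(names(features), c("match_id", "result"))
  x <- as.data.frame(features)[, cols, drop = FALSE]
  stopifnot(all(vapply(x, is.numeric, logical(1))))
  y <- features$result
  if (!all(y %in% 0:1)) stop("result must be 0/1")
  if (length(unique(y)) < 2) stop("both classes must be present")
  yf <- factor(y, levels = c(0, 1))
  n <- nrow(x)

  n_eval <- evaluation_fold_count(protocol)
  metrics <- matrix(NA_real_, n_eval, 5,
                    dimnames = list(NULL, c("accuracy", "precision", "recall",
                                            "f1", "mcc")))
  importance <- matrix(NA_real_, n_eval, ncol(x),
                       dimnames = list(NULL, cols))
  meta <- data.frame(repetition = integer(n_eval), fold = integer(n_eval),
                     config = integer(n_eval))
  row <- 0L
  skipped <- 0L
  for (r in seq_len(protocol$n_repeats)) {
    fold <- make_folds(n, protocol$n_folds, seed = r, y = y,
                       stratified = protocol$stratified)
    for (f in seq_len(protocol$n_folds)) {
      row <- row + 1L
      meta$repetition[row] <- r; meta$fold[row] <- f
      tr <- fold != f
      if (length(unique(y[tr])) < 2 || !any(!tr)) {
        skipped <- skipped + 1L
        next
      }
      # deterministic inner-split seed derived from (repetition, fold)
      g <- inner_grid_search(x[tr, , drop = FALSE], yf[tr], grid,
                             protocol$inner_folds, protocol$model_seed,
                             seed = 100000L + r * 1000L + f)
      fit <- fit_rf(x[tr, , drop = FALSE], yf[tr], grid[g, ],
                    protocol$model_seed)
      pred <- predict_rf(fit, x[!tr, , drop = FALSE])
      metrics[row, ] <- classification_metrics(y[!tr],
                                               as.integer(as.character(pred)))
      imp <- fit$variable.importance
      importance[row, ] <- if (sum(imp) > 0) imp / sum(imp) else imp
      meta$config[row] <- g
    }
  }
  if (skipped > 0)
    warning(skipped, " fold(s) skipped: single-class training data",
            call. = FALSE)
  structure(list(metrics = cbind(meta, as.data.frame(metrics)),
                 importance = importance,
                 protocol = protocol, grid_mode = grid_mode,
                 n = n, skipped = skipped,
                 alpha = attr(features, "alpha")),
            class = "edran_cv")
}

#' @export
print.edran_cv <- function(x, ...) {
  cat("edran_cv: ", x$protocol$n_repeats, " x ", x$protocol$n_folds,
      "-fold repeated CV (", nrow(x$metrics), " evaluations, grid: ",
      x$grid_mode, ")\n", sep = "")
  if (!is.null(x$alpha)) cat("  features: entropy order alpha =", x$alpha, "\n")
  print(summarize_metrics(x), digits = 4)
  invisible(x)
}

#' @export
summary.edran_cv <- function(object, ...) summarize_metrics(object)

#' Summarize metric distributions as mean, sd and 95% CI
#'
#' The confidence interval convention is the large-sample normal one used
#' throughout the reporting: `mean +/- 1.96 * sd / sqrt(n)` with the
#' `n - 1` sample standard deviation.
#'
#' @param x an `edran_cv` object, or a named list/data.frame of numeric
#'   metric vectors.
#' @return data.frame with one row per metric: `metric`, `mean`, `sd`,
#'   `ci_low`, `ci_high`, `n`.
#' @examples
#' # the CI the convention implies for mean 0.8061, sd 0.034, n = 250:
#' metric_ci(0.8061, 0.0340, 250)
#' @export
summarize_metrics <- function(x) {
  vals <- if (inherits(x, "edran_cv"))
    x$metrics[, c("accuracy", "precision", "recall", "f1", "mcc")]
  else as.data.frame(x)
  out <- do.call(rbind, lapply(names(vals), function(m) {
    v <- vals[[m]][!is.na(vals[[m]])]
    if (length(v) < 2) stop("metric ", m, ": need at least 2 values")
    cbind(data.frame(metric = m), metric_ci(mean(v), stats::sd(v), length(v)))
  }))
  rownames(out) <- NULL
  out
}

#' @rdname summarize_metrics
#' @param mean,sd,n summary ingredients of a metric distribution.
#' @export
metric_ci <- function(mean, sd, n) {
  half <- 1.96 * sd / sqrt(n)
  data.frame(mean = mean, sd = sd, ci_low = mean - half,
             ci_high = mean + half, n = n)
}

#' Welch two-sample comparison with Hedges' g
#'
#' Welch's unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and two-sided p-value, plus the bias-corrected standardized mean
#' difference: Cohen's d on the pooled standard deviation times the
#' small-sample correction `1 - 3 / (4 (n1 + n2) - 9)`. Signs follow
#' `mean(a) - mean(b)`.
#'
#' @param a,b numeric samples with at least 2 values each; at least one must
#'   have positive variance.
#' @return list with `mean_diff`, `t`, `df`, `p_value`, `hedges_g`.
#' @export
welch_compare <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("both samples need at least 2 values")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) stop("both samples have zero variance")
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  d <- (mean(a) - mean(b)) / sp
  g <- d * (1 - 3 / (4 * (na + nb) - 9))
  list(mean_diff = mean(a) - mean(b), t = t, df = df, p_value = p,
       hedges_g = g)
}

#' Bonferroni and Holm multiple-testing adjustment
#'
#' Bonferroni: `min(K p, 1)` with `K` the family size. Holm: the step-down
#' variant with enforced monotonicity, uniformly at least as powerful.
#' Output order matches input order.
#'
#' @param p raw p-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"holm"`.
#' @return adjusted p-values, same length and order as `p`.
#' @examples
#' adjust_pvalues(c(0.005, 0.01, 0.03, 0.04, 0.2), "holm")
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "holm")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Compare metric distributions across entropy orders against a baseline
#'
#' For each non-baseline order, compares its repeated-CV metric values to
#' the baseline's with [welch_compare()] and reports the mean difference,
#' Welch t, df, raw two-sided p, Hedges' g, and Bonferroni- and
#' Holm-adjusted p-values over the family of comparisons, with a
#' significance flag at family-wise 0.05 (Holm).
#'
#' @param cv_list named list of `edran_cv` objects, names identifying the
#'   entropy order (e.g. `"0"`, `"0.5"`, `"1"`).
#' @param baseline name of the baseline entry (default `"1"`, the Shannon
#'   order).
#' @param metric which metric to compare (default `"mcc"`, the
#'   imbalance-robust choice).
#' @return data.frame of class `edran_comparison`, one row per comparison.
#' @export
compare_alphas <- function(cv_list, baseline = "1", metric = "mcc") {
  stopifnot(baseline %in% names(cv_list))
  pull <- function(cv) {
    v <- cv$metrics[[metric]]
    v[!is.na(v)]
  }
  base_vals <- pull(cv_list[[baseline]])
  others <- setdiff(names(cv_list), baseline)
  rows <- lapply(others, function(nm) {
    w <- welch_compare(pull(cv_list[[nm]]), base_vals)
    data.frame(comparison = paste0("alpha=", nm, " vs alpha=", baseline),
               mean_diff = w$mean_diff, t = w$t, df = w$df,
               p_raw = w$p_value, hedges_g = w$hedges_g)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- adjust_pvalues(out$p_raw, "bonferroni")
  out$p_holm <- adjust_pvalues(out$p_raw, "holm")
  out$significant_holm <- out$p_holm < 0.05
  rownames(out) <- NULL
  class(out) <- c("edran_comparison", "data.frame")
  attr(out, "metric") <- metric
  out
}

#' Mean random-forest feature importance across evaluations
#'
#' @param cv an `edran_cv` with importance capture (always on).
#' @return data.frame per feature: mean and sd of the per-model normalized
#'   impurity importances (each model's importances sum to 1).
#' @export
feature_importance_summary <- function(cv) {
  stopifnot(inherits(cv, "edran_cv"))
  imp <- cv$importance[stats::complete.cases(cv$importance), , drop = FALSE]
  data.frame(feature = colnames(imp),
             mean_importance = colMeans(imp),
             sd_importance = apply(imp, 2, stats::sd),
             row.names = NULL)
}

#' @export
plot.edran_cv <- function(x, ...) {
  vals <- x$metrics[, c("accuracy", "precision", "recall", "f1", "mcc")]
  graphics::boxplot(vals, ylab = "metric value",
                    main = "Repeated-CV metric distributions", ...)
  invisible(x)
}
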