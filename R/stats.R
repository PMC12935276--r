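#' Winner and loser entropy curves over the match
#'
#' Re-labels each match's two entropy series by match role (winner/loser)
#' rather than Team A/B, then summarizes per order and interval: the mean and
#' standard deviation of winners' and losers' entropy, their per-interval
#' mean difference, and the running (cumulative) sum of that difference
#' across intervals. A positive cumulative curve says winners were, on
#' average, the spatially less predictable side up to that point of the
#' match.
#'
#' @param series an `edran_series` from [compute_edran_series()].
#' @return data.frame with one row per order x interval: `alpha`, `interval`,
#'   `mean_winner`, `sd_winner`, `mean_loser`, `sd_loser`, `diff`
#'   (mean winner - mean loser), `cum_diff`.
#' @export
winner_loser_curves <- function(series) {
  stopifnot(inherits(series, "edran_series"))
  results <- attr(series, "results")
  res <- results$result[match(series$match_id, results$match_id)]
  if (anyNA(res)) stop("every match needs a winner label")
  role <- ifelse((series$team == "A") == (res == 1), "winner", "loser")
  df <- data.frame(alpha = series$alpha, interval = series$interval,
                   role = role, H = series$H)
  stat <- function(r, f) {
    a <- stats::aggregate(H ~ alpha + interval, data = df[df$role == r, ],
                          FUN = f)
    a[order(a$alpha, a$interval), ]
  }
  mw <- stat("winner", mean); sw <- stat("winner", stats::sd)
  ml <- stat("loser", mean); sl <- stat("loser", stats::sd)
  out <- data.frame(alpha = mw$alpha, interval = mw$interval,
                    mean_winner = mw$H, sd_winner = sw$H,
                    mean_loser = ml$H, sd_loser = sl$H)
  out$diff <- out$mean_winner - out$mean_loser
  out$cum_diff <- stats::ave(out$diff, out$alpha, FUN = cumsum)
  rownames(out) <- NULL
  out
}

#' Shapiro-Wilk normality screen for a feature table
#'
#' Runs the Shapiro-Wilk test on each feature column and recommends
#' rank-based association measures when any feature departs from normality
#' at the 0.05 level. Constant (degenerate) features are reported with an
#' `NA` p-value and force the rank-based recommendation.
#'
#' @param x numeric matrix or data.frame of feature columns (at least 3
#'   rows). Shapiro-Wilk supports at most 5000 observations; larger samples
#'   are tested on an evenly-spaced subsample of 5000.
#' @return list with `p_values` (named per column) and `recommendation`
#'   (`"rank-based"` or `"parametric"`).
#' @export
normality_gate <- function(x) {
  x <- as.data.frame(x)
  x <- x[vapply(x, is.numeric, logical(1))]
  if (!ncol(x)) stop("no numeric feature columns")
  if (nrow(x) < 3) stop("Shapiro-Wilk needs at least 3 observations")
  p <- vapply(x, function(v) {
    v <- v[is.finite(v)]
    if (length(unique(v)) < 2) return(NA_real_)
    if (length(v) > 5000) v <- v[round(seq(1, length(v), length.out = 5000))]
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  rec <- if (any(is.na(p)) || any(p < 0.05, na.rm = TRUE)) "rank-based"
         else "parametric"
  list(p_values = p, recommendation = rec)
}

#' Spearman screen of entropy-difference features against the result
#'
#' Computes, per interval, the Spearman rank correlation (average ranks for
#' ties) between the interval's entropy-difference feature and the binary
#' match result, with the two-sided p-value, plus the mean correlation
#' across the ten intervals. Coefficients are reported unadjusted: this is a
#' screening profile, not a confirmatory test. A constant feature has no
#' defined rank correlation and is reported as `NA`.
#'
#' @param features an `edran_features` table from [delta_features()] (or any
#'   data.frame with `dH_t*` columns and a 0/1 `result`).
#' @return list of class `edran_correlation`: `profile` (data.frame
#'   `interval`, `rho`, `p_value`) and `mean_rho`.
#' @export
spearman_profile <- function(features) {
  cols <- grep("^dH_t", names(features), value = TRUE)
  if (!length(cols)) stop("no dH_t* feature columns found")
  y <- features$result
  if (length(unique(y)) < 2) stop("both result classes must be present")
  prof <- do.call(rbind, lapply(seq_along(cols), function(i) {
    v <- features[[cols[i]]]
    if (length(unique(v)) < 2)
      return(data.frame(interval = i, rho = NA_real_, p_value = NA_real_))
    ct <- suppressWarnings(
      stats::cor.test(v, y, method = "spearman", exact = FALSE))
    data.frame(interval = i, rho = unname(ct$estimate),
               p_value = ct$p.value)
  }))
  structure(list(profile = prof, mean_rho = mean(prof$rho, na.rm = TRUE)),
            class = "edran_correlation")
}

#' @export
print.edran_correlation <- function(x, ...) {
  cat("Spearman correlation of entropy-difference features with the result\n")
  print(format(x$profile, digits = 3), row.names = FALSE)
  cat("mean rho across intervals:", format(x$mean_rho, digits = 4), "\n")
  invisible(x)
}

#' Post-hoc power of the one-sample proportion test
#'
#' Power of the two-sided one-sample proportion test of H0: p = `p0` when
#' the true proportion is `p_obs`, used to judge whether a dataset's
#' win-rate imbalance was detectable at its sample size. The default
#' `"normal"` method is the unpooled normal approximation: critical bounds
#' are `p0 +/- z * sqrt(p0 (1 - p0) / n)` and the exceedance probability is
#' taken under `N(p_obs, p_obs (1 - p_obs) / n)`, both tails included. An
#' exact-binomial method is available for comparison.
#'
#' @param n number of matches.
#' @param p_obs observed proportion, strictly between 0 and 1.
#' @param p0 null proportion (default 0.5).
#' @param sig_level two-sided significance level (default 0.05).
#' @param method `"normal"` (default) or `"exact"`.
#' @return the power, a value in `[0, 1]`.
#' @examples
#' proportion_power(608, 342 / 608)  # about 0.87
#' proportion_power(374, 206 / 374)  # about 0.50: underpowered
#' @export
proportion_power <- function(n, p_obs, p0 = 0.5, sig_level = 0.05,
                             method = c("normal", "exact")) {
  method <- match.arg(method)
  if (n < 1) stop("n must be >= 1")
  if (p_obs <= 0 || p_obs >= 1 || p0 <= 0 || p0 >= 1)
    stop("proportions must lie strictly inside (0, 1)")
  z <- stats::qnorm(1 - sig_level / 2)
  se0 <- sqrt(p0 * (1 - p0) / n)
  if (method == "normal") {
    se1 <- sqrt(p_obs * (1 - p_obs) / n)
    lo <- p0 - z * se0
    hi <- p0 + z * se0
    stats::pnorm((lo - p_obs) / se1) + stats::pnorm((hi - p_obs) / se1,
                                                    lower.tail = FALSE)
  } else {
    # exact binomial: reject when the count falls outside the normal-bound
    # acceptance region, evaluated under Binomial(n, p_obs)
    lo_k <- ceiling(n * (p0 - z * se0)) - 1
    hi_k <- floor(n * (p0 + z * se0)) + 1
    stats::pbinom(lo_k, n, p_obs) +
      stats::pbinom(hi_k - 1, n, p_obs, lower.tail = FALSE)
  }
}
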