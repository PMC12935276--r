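#' Region-based cumulative possession matrices for one match
#'
#' For each team and each of the ten intervals, accumulates the durations of
#' the team's events into the pitch region where each event occurred: cell
#' `(r, c)` of the interval's matrix holds the total seconds of on-ball
#' activity the team spent in that region during the interval. Events are
#' assigned to intervals by their start time; durations are not split across
#' interval boundaries.
#'
#' @param dataset an [edran_dataset] (already filtered to on-ball events).
#' @param match_id which match to tabulate.
#' @param partition a [field_partition()].
#' @return a 4-d array `[n_rows, n_cols, interval, team]` of non-negative
#'   durations (20 matrices for the default scheme). The array sums to the
#'   match's total included event duration.
#' @export
accumulate_possession <- function(dataset, match_id,
                                  partition = field_partition()) {
  stopifnot(inherits(dataset, "edran_dataset"))
  ev <- dataset$events[dataset$events$match_id == match_id, , drop = FALSE]
  if (!match_id %in% dataset$results$match_id)
    stop("unknown match_id: ", match_id)
  scheme <- match_scheme(dataset, match_id)
  out <- array(0, dim = c(partition$n_rows, partition$n_cols, 10, 2),
               dimnames = list(NULL, NULL, paste0("t", 1:10), c("A", "B")))
  if (!nrow(ev)) return(out)
  reg <- region_of(ev$x, ev$y, partition)
  iv <- interval_of(ev$time_s, ev$period, scheme)
  ti <- match(ev$team, c("A", "B"))
  idx <- cbind(reg$row + 1L, reg$col + 1L, iv, ti)
  for (k in seq_len(nrow(ev)))
    out[idx[k, , drop = FALSE]] <- out[idx[k, , drop = FALSE]] + ev$duration_s[k]
  out
}

match_scheme <- function(dataset, match_id) {
  pe <- dataset$period_end
  pe <- pe[pe$match_id == match_id, ]
  ends <- pe$end_s[match(1:2, pe$period)]
  if (any(is.na(ends)))
    stop("match ", match_id, ": missing period ", which(is.na(ends))[1])
  build_interval_scheme(ends)
}

#' Normalize a possession matrix into a region probability distribution
#'
#' Divides the matrix by the team's total event duration in the interval. An
#' all-zero matrix (the team had no on-ball events in the interval) yields an
#' all-zero vector flagged as empty rather than an error; downstream entropy
#' records 0 for such intervals.
#'
#' @param m a non-negative matrix (one cell per region).
#' @return a `region_distribution`: list with `p` (flattened row-major
#'   probability vector) and logical `empty`.
#' @export
normalize_distribution <- function(m) {
  if (any(m < 0)) stop("possession matrix has negative cells")
  total <- sum(m)
  p <- if (total > 0) as.vector(t(m)) / total else as.vector(t(m)) * 0
  structure(list(p = p, empty = total == 0), class = "region_distribution")
}

#' Renyi entropy of a discrete distribution
#'
#' The order-`alpha` Renyi entropy `H_a(p) = log(sum_i p_i^a) / (1 - a)`,
#' with its three classical special cases handled explicitly:
#' * `alpha = 0` — Max (Hartley) entropy, the log of the number of regions
#'   with strictly positive probability (support breadth; no tolerance, true
#'   zeros stay zero because probabilities are exact duration ratios);
#' * `alpha` within `1e-9` of 1 — Shannon entropy `-sum p_i log p_i`, the
#'   L'Hopital limit, with `0 log 0 = 0`;
#' * `alpha = 2` — collision entropy `-log sum p_i^2` (via the general
#'   branch).
#' Zero probabilities are skipped for `alpha < 1` so the general branch is
#' well defined. Orders below 1 emphasize rare regions; orders above 1
#' emphasize dominant ones.
#'
#' @param p a probability vector summing to 1 (tolerance `1e-8`), or a
#'   `region_distribution` from [normalize_distribution()]. An empty
#'   distribution returns 0.
#' @param alpha entropy order, `>= 0`.
#' @param log_base base of the logarithm: `exp(1)` for nats (default) or 2
#'   for bits. All downstream uses (correlations, model features, orderings)
#'   are base-invariant.
#' @return the entropy, a value in `[0, log(length(p))]`.
#' @examples
#' renyi_entropy(rep(1 / 30, 30), 0)      # log(30), as at any order
#' renyi_entropy(c(0.75, 0.25), 2)        # -log(0.625)
#' @export
renyi_entropy <- function(p, alpha, log_base = exp(1)) {
  if (inherits(p, "region_distribution")) {
    if (p$empty) return(0)
    p <- p$p
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha))
    stop("alpha must be a single finite number")
  if (alpha < 0) stop("alpha must be >= 0")
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0))
    stop("p must be a non-negative numeric vector")
  if (sum(p) == 0) return(0)
  if (abs(sum(p) - 1) > 1e-8)
    stop("p is not normalized (sums to ", format(sum(p)), ")")
  pos <- p[p > 0]
  h <- if (alpha == 0) {
    log(length(pos))
  } else if (abs(alpha - 1) <= 1e-9) {
    -sum(pos * log(pos))
  } else {
    log(sum(pos^alpha)) / (1 - alpha)
  }
  h / log(log_base)
}

#' Event distribution randomness (EDRan) series for every match
#'
#' The pipeline's central quantity: for each match, team, interval and
#' entropy order, the Renyi entropy of the team's duration-weighted region
#' distribution in that interval. Intervals in which a team had no on-ball
#' events are recorded as entropy 0 with `empty = TRUE`.
#'
#' @param dataset a filtered [edran_dataset].
#' @param partition a [field_partition()].
#' @param alphas entropy orders; the default grid spans the Max-to-collision
#'   range studied for this metric.
#' @param log_base logarithm base (see [renyi_entropy()]).
#' @return an `edran_series`: a data.frame with columns `match_id`, `team`,
#'   `interval`, `alpha`, `H`, `dt_s`, `empty` (one row per combination),
#'   carrying the match labels and settings as attributes.
#' @export
compute_edran_series <- function(dataset, partition = field_partition(),
                                 alphas = c(0, 0.1, 0.5, 1, 1.5, 2),
                                 log_base = exp(1)) {
  stopifnot(inherits(dataset, "edran_dataset"))
  if (any(alphas < 0)) stop("alpha must be >= 0")
  ev <- dataset$events
  matches <- dataset$results$match_id

  # per-match interval schemes, stacked
  schemes <- lapply(matches, function(m) {
    s <- match_scheme(dataset, m); s$match_id <- m; s
  })
  scheme_tab <- do.call(rbind, schemes)

  reg <- region_of(ev$x, ev$y, partition)
  pkey <- paste(ev$match_id, ev$period)
  dt1 <- scheme_tab$dt_s[scheme_tab$interval == 1]
  dt6 <- scheme_tab$dt_s[scheme_tab$interval == 6]
  names(dt1) <- names(dt6) <- matches
  mi <- match(ev$match_id, matches)
  dt_ev <- ifelse(ev$period == 1, dt1[mi], dt6[mi])
  end_ev <- ifelse(ev$period == 1, dt1[mi] * 5, dt6[mi] * 5)
  if (any(ev$time_s > end_ev + 1e-9))
    stop("event beyond its period end in match ",
         ev$match_id[which(ev$time_s > end_ev + 1e-9)[1]])
  iv <- as.integer(pmin(floor(ev$time_s / dt_ev), 4) + 1L + (ev$period - 1L) * 5L)

  # total duration per (match, team, interval, region), then per group;
  # zero-duration cells are dropped so support counts stay exact
  cell <- rowsum(ev$duration_s,
                 group = paste(ev$match_id, ev$team, iv, reg$flat, sep = "\r"))
  cell <- cell[cell[, 1] > 0, , drop = FALSE]
  parts <- do.call(rbind, strsplit(rownames(cell), "\r", fixed = TRUE))
  cell_df <- data.frame(match_id = parts[, 1], team = parts[, 2],
                        interval = as.integer(parts[, 3]),
                        dur = cell[, 1], stringsAsFactors = FALSE)
  grp <- paste(cell_df$match_id, cell_df$team, cell_df$interval, sep = "\r")
  tot <- rowsum(cell_df$dur, grp)
  p <- cell_df$dur / tot[match(grp, rownames(tot)), 1]

  # full grid of match x team x interval
  grid <- expand.grid(interval = 1:10, team = c("A", "B"), match_id = matches,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("match_id", "team", "interval")]
  gk <- paste(grid$match_id, grid$team, grid$interval, sep = "\r")
  grid$dt_s <- scheme_tab$dt_s[match(paste(grid$match_id, grid$interval),
                                     paste(scheme_tab$match_id, scheme_tab$interval))]
  grid$empty <- !(gk %in% grp)

  grp_names <- rownames(rowsum(p, grp))
  out <- vector("list", length(alphas))
  for (j in seq_along(alphas)) {
    a <- alphas[j]
    h_grp <- if (a == 0) {
      log(as.vector(rowsum(rep(1, length(p)), grp)))
    } else if (abs(a - 1) <= 1e-9) {
      -as.vector(rowsum(p * log(p), grp))
    } else {
      log(as.vector(rowsum(p^a, grp))) / (1 - a)
    }
    names(h_grp) <- grp_names
    H <- h_grp[gk] / log(log_base)
    H[is.na(H)] <- 0
    block <- grid
    block$alpha <- a
    block$H <- unname(H)
    out[[j]] <- block
  }
  res <- do.call(rbind, out)
  res <- res[, c("match_id", "team", "interval", "alpha", "H", "dt_s", "empty")]
  rownames(res) <- NULL
  structure(res,
            class = c("edran_series", "data.frame"),
            results = dataset$results,
            partition = partition,
            alphas = alphas,
            log_base = log_base)
}

#' @export
print.edran_series <- function(x, ...) {
  cat("edran_series:", length(unique(x$match_id)), "matches x 2 teams x 10",
      "intervals x", length(attr(x, "alphas")), "orders (",
      nrow(x), "values )\n")
  cat("  alpha grid:", paste(attr(x, "alphas"), collapse = ", "), "\n")
  if (any(x$empty)) cat("  empty team-intervals:", sum(x$empty) /
                          length(attr(x, "alphas")), "\n")
  invisible(x)
}

#' Between-team entropy-difference features
#'
#' Reduces the 20 per-match entropy values at one order (2 teams x 10
#' intervals) to 10 features: the Team A minus Team B entropy difference per
#' interval, normalized by the interval duration,
#' `dH(t_i) = (H_A(t_i) - H_B(t_i)) / dt_i`. Duration normalization makes
#' intervals comparable across halves of different injury time. A positive
#' feature means Team A was the spatially less predictable side in that
#' interval.
#'
#' @param series an `edran_series` from [compute_edran_series()].
#' @param alpha which entropy order to extract (must be on the series grid).
#' @param dt_unit unit for the interval duration divisor: `"min"` (default;
#'   keeps features O(0.1)) or `"s"`.
#' @return an `edran_features` data.frame: `match_id`, `dH_t1` ... `dH_t10`,
#'   `result`.
#' @export
delta_features <- function(series, alpha, dt_unit = c("min", "s")) {
  stopifnot(inherits(series, "edran_series"))
  dt_unit <- match.arg(dt_unit)
  results <- attr(series, "results")
  sub <- series[abs(series$alpha - alpha) < 1e-12, , drop = FALSE]
  if (!nrow(sub)) stop("alpha ", alpha, " is not on the series grid")
  a <- sub[sub$team == "A", ]
  b <- sub[sub$team == "B", ]
  key <- function(d) paste(d$match_id, d$interval)
  b <- b[match(key(a), key(b)), ]
  if (anyNA(b$H)) stop("missing team B interval for some match")
  dt <- a$dt_s / if (dt_unit == "min") 60 else 1
  dH <- (a$H - b$H) / dt
  wide <- matrix(NA_real_, nrow = nrow(results), ncol = 10,
                 dimnames = list(NULL, paste0("dH_t", 1:10)))
  ri <- match(a$match_id, results$match_id)
  wide[cbind(ri, a$interval)] <- dH
  if (anyNA(wide)) stop("missing interval features for some match")
  out <- data.frame(match_id = results$match_id, wide, result = results$result)
  rownames(out) <- NULL
  structure(out, class = c("edran_features", "data.frame"),
            alpha = alpha, dt_unit = dt_unit)
}

#' @export
print.edran_features <- function(x, ...) {
  cat("edran_features: ", nrow(x), " matches, 10 interval features at alpha = ",
      attr(x, "alpha"), " (dt in ", attr(x, "dt_unit"), ")\n", sep = "")
  cat("  Team A win rate:", format(mean(x$result), digits = 4), "\n")
  invisible(x)
}
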