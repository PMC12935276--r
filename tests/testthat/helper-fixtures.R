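# In-code fixture builders shared across test files.

# A single valid event row with overridable fields.
make_event <- function(match_id = "m1", team = "A", period = 1L,
                       time_s = 10, duration_s = 2, x = 60, y = 40,
                       event_type = "pass") {
  data.frame(match_id = match_id, team = team, period = period,
             time_s = time_s, duration_s = duration_s, x = x, y = y,
             event_type = event_type, stringsAsFactors = FALSE)
}

# A hand-built one-match dataset: both teams, both halves, known durations.
toy_dataset <- function(result = 1L, period_end = c(2700, 2700)) {
  ev <- rbind(
    make_event(team = "A", period = 1, time_s = 10, duration_s = 3,
               x = 5, y = 5),
    make_event(team = "A", period = 1, time_s = 100, duration_s = 1,
               x = 10, y = 10),
    make_event(team = "A", period = 1, time_s = 200, duration_s = 4,
               x = 25, y = 5),
    make_event(team = "B", period = 1, time_s = 50, duration_s = 2,
               x = 60, y = 40),
    make_event(team = "A", period = 2, time_s = 30, duration_s = 2,
               x = 90, y = 70),
    make_event(team = "B", period = 2, time_s = 500, duration_s = 5,
               x = 110, y = 20, event_type = "carry"))
  edran_dataset(ev, data.frame(match_id = "m1", result = result),
                period_end = data.frame(match_id = "m1", period = 1:2,
                                        end_s = period_end))
}

# Random valid multi-match dataset for property checks (not via the
# simulator, so simulator and pipeline can cross-check each other).
random_dataset <- function(n_matches = 3, events_per_match = 40, seed = 1) {
  set.seed(seed)
  ev <- do.call(rbind, lapply(seq_len(n_matches), function(i) {
    n <- events_per_match
    make_event(match_id = paste0("r", i),
               team = sample(c("A", "B"), n, replace = TRUE),
               period = sample(1:2, n, replace = TRUE),
               time_s = runif(n, 0, 2700),
               duration_s = runif(n, 0.1, 8),
               x = runif(n, 0, 120), y = runif(n, 0, 80),
               event_type = sample(c("pass", "carry", "shot"), n, TRUE))
  }))
  edran_dataset(ev, data.frame(match_id = paste0("r", seq_len(n_matches)),
                               result = rep_len(c(1L, 0L), n_matches)))
}

# Dirichlet draw for entropy property tests.
rdirichlet_test <- function(n, theta = 1) {
  g <- rgamma(n, shape = theta)
  g / sum(g)
}

# Independent brute-force Renyi entropy oracle (log-sum formula evaluated
# directly, limits by explicit special-casing).
renyi_oracle <- function(p, alpha) {
  p <- p[p > 0]
  if (alpha == 0) return(log(length(p)))
  if (alpha == 1) return(-sum(p * log(p)))
  log(sum(p^alpha)) / (1 - alpha)
}

# Separable feature table: label is the sign of the feature sum, rows near
# the boundary removed so the margin is wide.
separable_features <- function(n = 400, margin = 2.5, seed = 42) {
  set.seed(seed)
  x <- matrix(rnorm(6 * n * 10), ncol = 10,
              dimnames = list(NULL, paste0("dH_t", 1:10)))
  s <- rowSums(x)
  keep <- which(abs(s) > margin)[seq_len(n)]
  data.frame(x[keep, ], result = as.integer(s[keep] > 0))
}
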