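test_that("possession matrices accumulate durations into the right cells", {
  # two team-A events in region (0,0) of t1 (3 s + 1 s) and one in (0,1) (4 s)
  d <- toy_dataset()
  m <- accumulate_possession(d, "m1")
  expect_equal(dim(m), c(5, 6, 10, 2))
  expect_equal(m[1, 1, 1, "A"], 4)
  expect_equal(m[1, 2, 1, "A"], 4)
  expect_equal(sum(m[, , 1, "A"]), 8)
  # team B has nothing in t7: an all-zero matrix, not an error
  expect_equal(sum(m[, , 7, "B"]), 0)
  # conservation across all 20 matrices
  expect_equal(sum(m), sum(d$events$duration_s))
})

test_that("possession totals conserve the included event duration on random data", {
  d <- random_dataset(n_matches = 4, events_per_match = 60, seed = 11)
  total <- sum(vapply(d$results$match_id,
                      function(m) sum(accumulate_possession(d, m)),
                      numeric(1)))
  expect_equal(total, sum(d$events$duration_s))
})

test_that("normalization yields a probability vector or an empty flag", {
  m <- matrix(0, 5, 6); m[1, 1] <- 4; m[1, 2] <- 4
  nd <- normalize_distribution(m)
  expect_false(nd$empty)
  expect_equal(nd$p[1:2], c(0.5, 0.5))
  expect_equal(sum(nd$p), 1, tolerance = 1e-12)
  z <- normalize_distribution(matrix(0, 5, 6))
  expect_true(z$empty)
  expect_equal(sum(z$p), 0)
  expect_error(normalize_distribution(matrix(-1, 2, 2)), "negative")
})

test_that("Renyi entropy reproduces its closed-form special cases", {
  u <- rep(1 / 30, 30)
  for (a in c(0, 0.1, 0.5, 1, 1.5, 2))
    expect_equal(renyi_entropy(u, a), log(30), tolerance = 1e-12)
  expect_equal(renyi_entropy(c(0.5, 0.5), 0), log(2))
  # frozen hand-derived values for p = (0.75, 0.25)
  expect_equal(renyi_entropy(c(0.75, 0.25), 2), 0.4700036292457356,
               tolerance = 1e-12)
  expect_equal(renyi_entropy(c(0.75, 0.25), 1), 0.5623351446188083,
               tolerance = 1e-12)
  # support counting ignores true zeros
  expect_equal(renyi_entropy(c(0.5, 0.5, 0, 0), 0), log(2))
  # base-2 option
  expect_equal(renyi_entropy(c(0.5, 0.5), 1, log_base = 2), 1)
  expect_equal(renyi_entropy(normalize_distribution(matrix(0, 5, 6)), 1), 0)
  expect_error(renyi_entropy(c(0.5, 0.5), -0.1), "alpha")
  expect_error(renyi_entropy(c(0.5, 0.6), 1), "not normalized")
})

test_that("entropy matches a brute-force oracle and its order/permutation properties", {
  grid <- c(0, 0.1, 0.5, 1, 1.5, 2)
  set.seed(101)
  for (i in 1:200) {
    n <- sample(2:30, 1)
    p <- rdirichlet_test(n, theta = runif(1, 0.2, 3))
    if (runif(1) < 0.3) {          # plant exact zeros
      z <- sample(n, sample(0:(n - 1), 1))
      p[z] <- 0; p <- p / sum(p)
    }
    h <- vapply(grid, function(a) renyi_entropy(p, a), numeric(1))
    ho <- vapply(grid, function(a) renyi_oracle(p, a), numeric(1))
    expect_equal(h, ho, tolerance = 1e-10)
    # bounds and monotone non-increase in the order
    expect_true(all(h >= -1e-12 & h <= log(length(p)) + 1e-12))
    expect_true(all(diff(h) <= 1e-10))
    # continuity across the Shannon limit
    expect_lt(abs(renyi_entropy(p, 1 - 1e-6) - renyi_oracle(p, 1)), 1e-4)
    expect_lt(abs(renyi_entropy(p, 1 + 1e-6) - renyi_oracle(p, 1)), 1e-4)
    # permutation invariance
    expect_equal(renyi_entropy(sample(p), 0.5), renyi_entropy(p, 0.5))
  }
})

test_that("the series has one value per match x team x interval x order", {
  d <- toy_dataset()
  s <- compute_edran_series(d, alphas = c(0, 1, 2))
  expect_equal(nrow(s), 2 * 10 * 3)
  expect_true(all(s$H >= 0 & s$H <= log(30)))
  # intervals with no events are flagged empty with H = 0
  expect_true(all(s$H[s$empty] == 0))
  expect_true(any(s$empty))
  # interval durations come from the match's halves
  expect_equal(unique(s$dt_s), 540)
})

test_that("series entropies agree with direct per-interval computation", {
  d <- random_dataset(n_matches = 3, events_per_match = 80, seed = 5)
  s <- compute_edran_series(d, alphas = c(0, 0.7, 1, 2))
  for (m in d$results$match_id) {
    poss <- accumulate_possession(d, m)
    for (team in c("A", "B")) for (t in c(1, 4, 9)) {
      nd <- normalize_distribution(poss[, , t, team])
      for (a in c(0, 0.7, 1, 2)) {
        got <- s$H[s$match_id == m & s$team == team & s$interval == t &
                     s$alpha == a]
        expect_equal(got, renyi_entropy(nd, a), tolerance = 1e-10)
      }
    }
  }
})

test_that("a team confined to one region scores zero entropy at every order", {
  ev <- do.call(rbind, lapply(seq(50, 2650, length.out = 12), function(tm)
    rbind(make_event(team = "A", period = 1, time_s = tm, x = 5, y = 5),
          make_event(team = "A", period = 2, time_s = tm, x = 5, y = 5),
          make_event(team = "B", period = 1, time_s = tm, x = runif(1, 0, 120),
                     y = runif(1, 0, 80)),
          make_event(team = "B", period = 2, time_s = tm, x = runif(1, 0, 120),
                     y = runif(1, 0, 80)))))
  d <- edran_dataset(ev, data.frame(match_id = "m1", result = 1))
  s <- compute_edran_series(d, alphas = c(0, 0.5, 1, 2))
  expect_true(all(s$H[s$team == "A"] == 0))
  expect_true(any(s$H[s$team == "B"] > 0))
})

test_that("delta features are duration-normalized antisymmetric differences", {
  d <- random_dataset(n_matches = 4, events_per_match = 100, seed = 9)
  s <- compute_edran_series(d, alphas = c(0, 1))
  f <- delta_features(s, 1)
  expect_equal(dim(f), c(4, 12))
  # recompute one entry by hand from the series
  m <- d$results$match_id[1]
  ha <- s$H[s$match_id == m & s$team == "A" & s$interval == 3 & s$alpha == 1]
  hb <- s$H[s$match_id == m & s$team == "B" & s$interval == 3 & s$alpha == 1]
  dt_min <- s$dt_s[s$match_id == m & s$team == "A" & s$interval == 3 &
                     s$alpha == 1] / 60
  expect_equal(f$dH_t3[f$match_id == m], (ha - hb) / dt_min)

  # swapping team labels negates every feature
  d2 <- d
  d2$events$team <- ifelse(d$events$team == "A", "B", "A")
  f2 <- delta_features(compute_edran_series(d2, alphas = c(0, 1)), 1)
  expect_equal(as.matrix(f2[, paste0("dH_t", 1:10)]),
               -as.matrix(f[, paste0("dH_t", 1:10)]), tolerance = 1e-12)

  # seconds option scales by 60
  fs <- delta_features(s, 1, dt_unit = "s")
  expect_equal(as.matrix(fs[, paste0("dH_t", 1:10)]) * 60,
               as.matrix(f[, paste0("dH_t", 1:10)]), tolerance = 1e-12)
  expect_error(delta_features(s, 0.25), "not on the series grid")
})

test_that("identical team entropies give all-zero features at the stated scale", {
  # H_A = 3.0, H_B = 2.5, dt = 9.4 min -> 0.0532 per minute
  expect_equal((3.0 - 2.5) / 9.4, 0.05319148936170213)
  # mirror-image events: both teams identical spatial play
  ev <- rbind(make_event(team = "A", x = 5, y = 5),
              make_event(team = "B", x = 5, y = 5),
              make_event(team = "A", period = 2, x = 50, y = 50),
              make_event(team = "B", period = 2, x = 50, y = 50))
  d <- edran_dataset(ev, data.frame(match_id = "m1", result = 1))
  f <- delta_features(compute_edran_series(d, alphas = 0), 0)
  expect_equal(unname(as.matrix(f[, paste0("dH_t", 1:10)])),
               matrix(0, 1, 10))
})
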