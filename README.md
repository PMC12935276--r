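# edran — spatial event-distribution randomness for football

`edran` quantifies how unpredictably a football team distributes its
on-ball events over the pitch and relates that randomness to match
outcomes. It is written for sports-performance analysts working with event
logs (the standard 120 × 80 event-coordinate schema) who want a temporal,
score-independent team performance metric.

The core quantity is **EDRan** (Event Distribution Randomness): the pitch
is tiled into 30 equal-area regions; each half, including injury time, is
split into five equal intervals; per team and interval, event durations
accumulate into a region-based cumulative possession matrix, which is
normalized into a probability distribution `p`; and its randomness is the
order-α Rényi entropy

    H_α(p) = log(Σ_i p_i^α) / (1 − α)

with Max/Hartley entropy (α = 0, the log of the number of regions used),
Shannon entropy (α → 1) and collision entropy (α = 2) as special cases.
The order α decides whether rarely used regions count as much as dominant
ones — the modelling question the package exists to probe. Matches are then
represented by ten features

    ΔH_α(t_i) = (H_α^A(t_i) − H_α^B(t_i)) / δt_i ,

the between-team entropy difference per interval normalized by the
interval duration, which are screened with Spearman correlation and fed to
random-forest match-winner models compared across α under a repeated
cross-validation protocol (50 × 5-fold, fold-internal grid search, Welch
tests on MCC with Hedges' g and Bonferroni/Holm corrections).

A synthetic labelled match-event generator with a controllable
spatial-breadth mechanism makes the entire pipeline testable without any
external data. See `vignettes/edran-methods.Rmd` for the methods account.

## Worked example

Simulate 150 labelled matches whose winners tend to use more of the pitch,
run the pipeline, and compare entropy orders:

```r
library(edran)

sim <- simulate_dataset(simulation_config(n_matches = 150, seed = 7))
d   <- filter_ball_movement_events(sim$dataset, quiet = TRUE)
d
#> edran_dataset: 150 matches, 134954 events
#>   Team A win rate: 0.5

s  <- compute_edran_series(d, alphas = c(0, 1, 2))
f0 <- delta_features(s, 0)           # Max-entropy features, per minute
round(spearman_profile(f0)$mean_rho, 3)
#> [1] 0.22

cv0 <- repeated_cv_evaluate(f0, cv_protocol(5, 5))
print(summarize_metrics(cv0), digits = 3)
#>      metric  mean     sd ci_low ci_high  n
#> 1  accuracy 0.640 0.0624  0.616   0.664 25
#> 2 precision 0.652 0.1099  0.609   0.695 25
#> 3    recall 0.627 0.0949  0.590   0.664 25
#> 4        f1 0.631 0.0649  0.605   0.656 25
#> 5       mcc 0.284 0.1364  0.231   0.338 25

cv1 <- repeated_cv_evaluate(delta_features(s, 1), cv_protocol(5, 5))
cv2 <- repeated_cv_evaluate(delta_features(s, 2), cv_protocol(5, 5))
print(as.data.frame(compare_alphas(list("0" = cv0, "1" = cv1, "2" = cv2),
                                   baseline = "1")), digits = 3)
#>           comparison mean_diff      t   df p_raw hedges_g p_bonferroni p_holm
#> 1 alpha=0 vs alpha=1    0.0686  1.596 46.2 0.117   0.4443        0.235  0.235
#> 2 alpha=2 vs alpha=1   -0.0109 -0.213 46.8 0.833  -0.0592        1.000  0.833
```

Reading the output: the Max-entropy (α = 0) features correlate positively
with winning (mean Spearman ρ = 0.22 across the ten intervals) and support
a classifier well above chance (mean MCC 0.28 over 25 held-out folds);
relative to the Shannon baseline, α = 0 gains ~0.07 MCC on this simulated
dataset while α = 2 does not — the breadth signal planted by the generator,
recovered by the order designed to see it. (At this short 5 × 5 protocol
the Welch comparison is not yet significant; the full 50 × 5 protocol
sharpens it.)

Dataset adequacy is assessed with the post-hoc power of the win-rate
proportion test, e.g. for 608 matches with 342 Team A wins:

```r
round(proportion_power(608, 342/608), 3)
#> [1] 0.871
```

A command-line wrapper over the same functions is installed at
`inst/cli/edran` (subcommands `simulate`, `ingest`, `compute`, `features`,
`correlate`, `power`, `evaluate`, `compare`, `report`; every run writes a
content-hash manifest).

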