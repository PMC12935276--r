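---
title: "Quantifying spatial event-distribution randomness with Renyi entropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spatial event-distribution randomness with Renyi entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edran)
```

## The problem

Football is a low-scoring invasion sport, so score-based performance metrics
are noisy. One alternative is to ask how *predictably* a team moves the ball
in space: a side that concentrates its on-ball activity in a few pitch zones
is easier to defend against than one that spreads activity widely and
unpredictably. `edran` quantifies this as **Event Distribution Randomness
(EDRan)**: the entropy of a team's duration-weighted spatial distribution of
on-ball events over pitch regions within a time interval, and relates it to
match outcomes.

The central modelling question is *which* entropy. Shannon entropy weights
every region in proportion to its usage probability. But teams differ in
whether they dominate a few favourite zones or use the whole pitch, and those
two styles are distinguished by the **Renyi family**

$$H_\alpha(p) = \frac{1}{1-\alpha}\,\log \sum_{i=1}^{n} p_i^{\alpha},$$

whose order $\alpha$ tunes the sensitivity to rare versus dominant regions:

* $\alpha = 0$ (Max/Hartley entropy) counts the regions with non-zero
  probability — pure support breadth, blind to how unevenly they are used;
* $\alpha \to 1$ is the Shannon limit;
* $\alpha = 2$ (collision entropy) $-\log \sum_i p_i^2$ is dominated by the
  most-used regions.

The package computes EDRan across the order grid
$\alpha \in \{0, 0.1, 0.5, 1, 1.5, 2\}$ and compares, by correlation
screening and by match-winner modelling, whether breadth-weighted or
dominance-weighted randomness is the better performance signal.

## From event logs to entropy series

**Input schema.** One flat row per on-ball event: match id, possessing team
("A"/"B"), period (1/2), start time within the period (s), duration (s),
location on the standard 120 × 80 event grid (already oriented toward the
possessing team's attack — the package never flips coordinates), and an
event-type tag. Labels are binary (1 = Team A won); drawn matches are not
representable and must be excluded upstream, which `edran_dataset()`
enforces with an explicit error.

**On-ball filter.** Because the analysis weights events by duration,
off-ball events are excluded. No canonical list of on-ball types exists in
event-log data, so `event_filter_config()` defaults to
pass/carry/dribble/shot/clearance/goalkeeper-distribution and is fully
configurable. Zero-duration events carry no possession weight and are
dropped by default.

**Partition.** `field_partition()` tiles the pitch into equal-area
rectangles — 5 rows × 6 columns = 30 regions by default (each third of the
pitch split into 10 cells). Equal areas matter: unequal cells would bias the
entropy. Binning is half-open with the upper pitch boundary closed, rows
from `y`, columns from `x`, flat index row-major and zero-based, so the
usual region-numbering diagram is reproducible. Coarser (3 × 5) and finer
(8 × 12) partitions are supported; the 30-region default balances
informative against sparse distributions.

**Intervals.** `build_interval_scheme()` splits each half — *including its
injury time* — into five equal contiguous intervals, ten per match. Halves
are never mixed: an interval belongs entirely to one half, so the distinct
dynamics around half-time are preserved and interval lengths may differ
between halves. Events are assigned to the interval containing their start
time; durations are not split across boundaries (events spanning a boundary
are rare and short relative to a ~9-minute interval, and splitting would
complicate the conservation property for no measurable gain).

**Possession matrices and distributions.** Per team and interval, event
durations accumulate into the region cells (`accumulate_possession()`), and
the matrix is normalized by the team's total duration in the interval
(`normalize_distribution()`). The per-interval totals over all 20 matrices
exactly conserve the match's included event duration — a tested invariant.
A team with no events in an interval yields an *empty* distribution: its
entropy is recorded as 0 with an `empty` flag (and the difference feature
uses 0), which keeps the 10-feature shape the models require rather than
propagating missingness.

**Entropy.** `renyi_entropy()` implements the three closed-form branches
explicitly. Numerical choices: the Shannon branch is taken when
$|\alpha - 1| \le 10^{-9}$ (with $0\log 0 = 0$); support counting at
$\alpha = 0$ uses strict $p_i > 0$ with no tolerance — probabilities are
exact ratios of duration sums, so true zeros survive the division; zero
probabilities are skipped for $\alpha < 1$ so the general branch is
defined. Logarithms are natural (nats) by default with base 2 available;
every downstream use (correlations, features, orderings) is base-invariant.
Property tests check the entropy bounds $0 \le H_\alpha \le \log n$,
monotone non-increase in $\alpha$, permutation invariance, and continuity
through the Shannon limit against a brute-force oracle.

## Features, screening and curves

The 20 per-match values at one order are reduced to 10 features
(`delta_features()`):

$$\Delta H_\alpha(t_i) = \frac{H_\alpha^A(t_i) - H_\alpha^B(t_i)}{\delta t_i},$$

the between-team entropy difference normalized by the interval duration
$\delta t_i$, which makes intervals comparable across halves with different
injury time. The duration unit is **minutes** by default (features are then
O(0.1), a convenient scale); seconds are available. The unit only rescales
features — rank correlations and tree models are unaffected.

`winner_loser_curves()` re-labels each match by role (winner/loser) and
reports per-interval means, standard deviations, and the running sum of the
winner-minus-loser mean difference (the "cumulative" curve is the running
sum of per-interval means; the alternative sum-over-matches reading
coincides up to scaling). `normality_gate()` (Shapiro–Wilk per feature)
motivates rank-based screening; `spearman_profile()` reports the Spearman
$\rho$ of each feature against the label with unadjusted p-values —
deliberately so, since this stage is a screen, not a confirmatory family.

`proportion_power()` assesses dataset adequacy: the post-hoc power of the
two-sided one-sample proportion test of the Team A win rate against
$p_0 = 0.5$. The default is the unpooled normal approximation — critical
bounds $p_0 \pm z_{0.975}\sqrt{p_0(1-p_0)/n}$, exceedance probability under
$N(p_{\mathrm{obs}}, p_{\mathrm{obs}}(1-p_{\mathrm{obs}})/n)$, both tails —
with an exact-binomial option for comparison. At 608 matches with a 0.5625
win rate this gives ≈ 0.87; at 374 matches with 0.5508 it gives ≈ 0.50
(underpowered).

## The model-comparison protocol

`repeated_cv_evaluate()` estimates a random forest's out-of-sample
performance per entropy order with 50 repetitions of shuffled 5-fold
cross-validation (250 held-out evaluations). Design points:

* **Seeding.** Repetition $r$ shuffles with seed $r$; the forest seed is
  fixed at 42 for every fit; inner-CV splits are derived deterministically
  from (repetition, fold). The whole run is bit-deterministic given the
  data and protocol — a tested contract.
* **Tuning without leakage.** Each evaluation grid-searches its own
  training folds with an inner 5-fold CV scored by accuracy, then refits
  the winning configuration on the full training folds. The inner fold
  count is a package default; only the outer protocol determines the
  published degrees of freedom (two 250-value samples give Welch df ≈ 498).
* **Backend.** Forests are fit with `ranger`; the grid axes map as
  trees → `num.trees`, max depth → `max.depth` (0 = unlimited),
  min samples to split → `min.node.size`, min leaf size → `min.bucket`,
  bootstrap on/off → `replace` with `sample.fraction = 1`. The `reduced`
  grid (100 trees, depth ∈ {unlimited, 10}, defaults elsewhere) preserves
  the tuning machinery at simulation scale; the `full` grid (216
  configurations) is available for real-data runs.
* **Folds.** Outer folds are plain shuffled k-fold; stratification is
  available by flag but off by default. At 300+ matches and a ~55/45
  balance, single-class training folds essentially never occur; if one
  does, the fold is skipped with a warning and recorded as missing.
* **Metrics.** Accuracy, precision, recall, F1 (positive class: Team A
  win; empty-denominator conventions give 0) and MCC, the
  imbalance-robust comparison metric. Summaries use
  mean ± 1.96 sd/√n confidence intervals.

`compare_alphas()` runs Welch's unequal-variance t-test of each order's MCC
distribution against the Shannon baseline, with Hedges'
$g = d_{\mathrm{pooled}} \times (1 - 3/(4(n_1+n_2)-9))$, and controls the
family-wise error with both Bonferroni ($\min(Kp, 1)$) and Holm step-down
corrections; Holm is uniformly at least as powerful, which the tests verify
on random p-vectors.

## The synthetic generator

`simulate_dataset()` exists so every stage — and the breadth-versus-
dominance question itself — is testable without any external download. It
emulates the statistical structure the analysis assumes, not football
tactics:

* **Spatial style** is a match-level trait: each team draws one symmetric
  Dirichlet($\theta$) preference over the 30 regions per match
  ($\theta = 0.8$ by default: moderately concentrated play, so realized
  usage is uneven, as real possession maps are). Intervals differ only
  through finite event sampling.
* **Breadth signal** (default): a fair coin designates the stronger team;
  the weaker team has `breadth_gap` (default 8) randomly chosen regions
  masked out of its play. Support breadth — exactly what Max entropy
  measures — is then the planted discriminative quantity, while the
  within-support unevenness noise handicaps the higher orders.
* **Outcome link:** $P(\text{A wins}) = \mathrm{logistic}(\beta s)$ with
  $\beta = 3$ and $s$ the true mean per-interval Max-entropy gap in nats.
  The gap is deliberately *not* duration-normalized: a team's win
  propensity should not depend on how much injury time happened to be
  played. With the defaults, win probabilities span roughly 0.3–0.7.
* **Late-game narrowing:** in intervals 8–10 the masked-region count is
  shrunk by the damping factor (default 0.5), reproducing the observed
  contraction of the winner–loser randomness gap late in matches (tested
  via the cumulative curves).
* **Counts and durations:** events per team-interval are Poisson(45);
  durations are Gamma(shape 2, scale 1.2 s) — Gamma rather than
  exponential so near-zero durations do not dominate after the
  zero-duration filter; halves last 2700 s plus Uniform(0, 300) s injury
  time.
* **Reproducibility:** one global seed feeds per-match substreams, so any
  match regenerates independently and whole logs are byte-identical across
  runs.

Alternative mechanisms are built in for contrast: `"concentration"` plants
the signal in how evenly a *fixed* support is used (each team draws its own
$\theta$; the link runs through collision entropy), and `"none"` severs the
link entirely.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: pass networks, formations, score-state feedback,
home advantage, team identity across matches, or any spatial
autocorrelation between consecutive events. Conclusions from the synthetic
pipeline are about the *method* (that it recovers a planted breadth signal
and ranks entropy orders accordingly), not about football.

## Problem sizes, variability and limitations

The simulation-based checks run at 600 matches with the reduced grid and a
5 × 5 protocol — large enough that the planted ordering
MCC($\alpha$=0) > MCC($\alpha$=2) and the positive Spearman screen emerge
clearly, small enough that the whole suite runs on a laptop in a few
minutes. Two Monte-Carlo facts are worth knowing:

* At this scale the mean MCC of a null (label-shuffled) run has a standard
  error of roughly 0.03–0.04, so a |mean MCC| < 0.05 check on a single
  shuffle passes with high but not total probability over seeds.
* The planted MCC ordering holds in expectation, with a typical gap of
  0.02–0.11 across replicate datasets; an individual 600-match dataset can
  occasionally reverse it, just as an individual real dataset could.

Other known limitations: the on-ball type list is a documented default, not
ground truth; events spanning interval boundaries are assigned wholly to
their starting interval; empty team-intervals contribute zeros rather than
missing values; draws and extra time are out of scope by design; and the
correlation screen is unadjusted for multiplicity. The repeated-CV protocol
shares data across repetitions, so its 250 values are not independent —
the Welch comparisons inherit the same optimism any repeated-CV comparison
has, which is why they are interpreted comparatively (order vs order on the
same data), never as absolute performance claims.
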