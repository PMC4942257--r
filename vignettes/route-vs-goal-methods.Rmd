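---
title: "Methods: route versus goal coding analysis for place cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: route versus goal coding analysis for place cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(routecells)
```

## The scientific question

Hippocampal place cells often fire at different rates when an animal passes
through the *same* location on its way to *different* destinations
("splitter" or differential firing). Two accounts compete: the cell may
encode the **route** being executed, or the **goal** being approached. The
two are confounded on most mazes because each goal is reached by exactly one
route. `routecells` implements the analysis for a maze that breaks the
confound: a start box leads through a central stem and left/right stems to
three goal boxes, with **two distinct routes (2 and 3) converging on the
shared Centre Goal Box**. Route coding predicts different firing on routes 2
and 3; goal coding predicts identical firing on both, different from routes
1 and 4.

The package implements every stage needed to answer the question from raw
tracking and spike times: rate maps and place-cell criteria, cluster-quality
metrics, three per-cell differential-firing tests with covariate control,
population pattern statistics, ensemble population-vector decoding against
shuffle nulls, a goal-box similarity analysis, and behavioural scoring of
the win-stay task — plus a synthetic-data generator so every stage runs and
can be validated with known ground truth.

## The maze and the simulator

`build_maze_layout()` constructs a canonical 14-sector maze from the
apparatus dimensions: seven octagonal enclosures (25 × 25 cm bounding box)
— start box, three choice points, three goal boxes — joined by seven
20 × 10 cm alleys. The layout is a fan with 45° diagonals so every alley
joins flat octagon faces and all centre-to-centre spans equal 45 cm. The
origin is the start-box centre; y grows toward the goals. Coordinates are
a package choice: the source experiment specifies only the dimensions.

Sector membership uses an even–odd ray-crossing test with a half-open
boundary convention, so a point on an edge shared by two sectors belongs to
exactly one of them, and spikes and tracking samples are assigned
identically. The same rule applies to spike positions interpolated onto a
sector boundary.

`simulate_session()` emulates the win-stay task. A session is
`n_blocks = 4` blocks. Within a block one route is rewarded; for the Centre
Goal Box a transparent barrier leaves only one of routes 2/3 open, chosen by
the rewarded route. The simulated rat starts each block with the win-stay
belief (the previously rewarded goal), then searches by elimination over
unvisited goals; from the first correct trial it completes
`trials_per_block = 11` trials (the first correct counts as the first),
making confusion errors with probability `p_post = 0.05`, biased
`sibling_weight = 4`-fold toward confusing routes 2 and 3 — the error
structure observed behaviourally. Tunable parameters, with defaults chosen
to match the recorded sessions:

* `inter_trial_hold = c(6, 9)` s — start-box holds (observed mean ≈ 9.3 s,
  minimum 6 s);
* `speed_profile = 25` cm/s — gives ≈ 5.4 s start-to-goal runs, matching
  observed post-identification travel times;
* `position_rate = 50` Hz — a typical camera tracking rate; the source
  does not state one.

Runs follow the route centerline with AR(1) speed noise and ±3 cm lateral
jitter; holds are AR(1) jitter about the start-box centre; correct trials
end with a 3–5 s reward dwell in the goal box. The carry back to the start
box is included (phase `"hold"`, `trial_id = NA`) so the position stream has
no gaps; runs toward the blocked central entrance stop at the barrier.

`simulate_place_cell()` draws spikes from an inhomogeneous Poisson process
by thinning, with intensity

$$\lambda(t) = b + p\,e^{-\|pos(t)-c\|^2/(2\sigma^2)}
  \cdot g_{route(t)} \cdot g_{goal(t)},$$

interpolated linearly between tracking samples. The route/goal gains
modulate the approach (hold and run phases) but **not** the goal-box dwell,
so goal-box firing is route-invariant by construction — the generator
contract the goal-box analysis tests against. Outside trials the gain is 1.
A route-specific cell raises one `route_gains` entry; a goal-dependent cell
raises one `goal_gains` entry, and because routes 2 and 3 share the centre
goal, the centre gain applies identically to both. The validation analyses
use gain 4 on a 4 Hz peak over a 0.2 Hz baseline
(`route_coded_population()`, `goal_coded_population()`,
`null_population()`, `goalbox_population()`).

What the generator does **not** emulate: theta rhythmicity and phase
precession, firing-rate drift within a session, anything about the decision
process of a real rat beyond win-stay-with-confusions, overdispersed
(non-Poisson) spiking, and cluster-cutting artefacts. Passing the recovery
suites therefore shows the *analysis chain* is correct and calibrated under
its stated assumptions, not that real recordings satisfy those assumptions.

## Rate maps, spatial information, place fields

`compute_rate_map()` estimates the firing rate on a square grid (bin size
2.5 cm, equal to the smoothing factor — the bin size is a package choice,
the smoothing factor `h = 2.5` cm is the published one) as

$$\lambda(x) = \sum_i g\!\left(\tfrac{s_i - x}{h}\right) \Big/
  \int_0^T g\!\left(\tfrac{y(t) - x}{h}\right)\,dt,
  \qquad g(u) = e^{-u^2/2},$$

with spike positions interpolated at spike times and the occupancy integral
taken by the rectangle rule over tracking samples (sub-sample interpolation
is not attempted). Bins with no tracking sample within 5 cm are masked
unvisited.

Spatial information (`spatial_information()`) is
$\sum_i P_i (R_i/R)\log_2(R_i/R)$ in **bits per spike**, with $P_i$ the
*raw* (unsmoothed) occupancy probability over visited bins, $R$ the
occupancy-weighted mean rate, and $0\log 0 = 0$. Whether the original
occupancy used smoothed or raw dwell is unstated; raw is used here and
makes the uniform-map value exactly zero.

Place fields (`count_place_fields()`) are 4-connected components of bins at
≥ 20% of the peak rate with ≥ 4 bins — thresholds are declared package
defaults, since no published criteria exist. Place-cell screening
(`classify_place_cell()`) applies the published strict thresholds: waveform
width > 250 µs, 0.1 Hz < mean rate < 5 Hz, information > 0.5 bits/spike.

## Cluster quality

For a cluster $C$ with $n_c$ spikes, with $D^2$ the squared Mahalanobis
distance to the cluster centre in the metric of the cluster's sample
covariance (no shrinkage; a singular covariance flags the metrics
undefined):

* isolation distance — the $n_c$-th smallest non-cluster $D^2$ (undefined
  when fewer non-cluster spikes exist than $n_c$);
* $L = \sum_{i \notin C}\left[1 - \mathrm{CDF}_{\chi^2_{df}}(D_i^2)\right]$
  and $L_{ratio} = L / n_c$, with `df` equal to the feature dimension
  (8 for tetrode feature sets);
* signal-to-noise — $(\mu_{signal}/\mu_{noise})^2$, which is the algebraic
  reduction of the impedance-matched definition; mean *peak* amplitude is
  used, since the alternative (mean absolute amplitude) is not specified.

`quality_effect_association()` guards against differential firing being a
sorting artefact: Kolmogorov–Smirnov comparisons of each metric between
differential and non-differential cells, and Spearman correlations between
each metric and the ANCOVA F statistic after iterative Grubbs outlier
removal (two-sided, α = 0.05, one point per iteration — the iteration
scheme is a package choice; the critical value uses the standard t-based
closed form).

## Differential-firing tests

For each place cell active in an analysed sector (start box, central stem,
left/right stems; active = pooled mean rate **strictly** above 1 Hz on at
least one route), `sector_trial_stats()` produces one row per (correct)
trial: firing rate (spikes in sector / time in sector), mean x, mean y, and
mean speed (path length / time). Error trials are excluded by default
(configurable); routes need ≥ 5 trials to enter a test (the protocol
guarantees ≥ 6 correct per block).

**Method 1, `ranked_ancova()`** (the primary test): replace rate and the
three covariates by mid-ranks; regress ranked rate on ranked covariates
(ignoring route); one-way ANOVA of the residuals against route. When the
omnibus p < α, the six pairwise comparisons of residual marginal means are
run with Tukey–Kramer adjustment (default; Šidák available — the original
adjustment is unstated, and Šidák is what its behavioural analyses used).
Degenerate inputs: an all-tied rate vector returns F = 0, p = 1; collinear
covariates are dropped with a warning.

**Method 2, `permutation_ancova()`**: parametric ANCOVA F for route
(rate on covariates + route), compared with `k = 5000` shuffles of the rate
vector against the fixed design; $p = \#\{F_{shuff} \ge F_{obs}\}/k$, so
the resolution is $1/k$ and an observed F above every shuffle reports
exactly 0.

**Method 3, `poisson_glm_differential()`**: log-link Poisson regression.
The faithful reading models per-trial spike counts with log exposure offset
(default); a raw-rate quasi-Poisson option exists for literal replication.
The omnibus route test is the deviance-reduction (likelihood-ratio)
statistic referred to an **F distribution with estimated dispersion**: at
session-sized trial counts (~43) the χ² reference for the plain LRT is
measurably liberal (≈ 0.065 rejection at α = 0.05 under the null
generator) while the F form stays within calibration bounds — a standard
small-sample safeguard for Poisson models. Post-hocs are six Mann–Whitney U
tests on raw rates (unadjusted by default, the literal reading).

**Classification** (`classify_route_goal()`): *route-specific k* — route k
differs (post-hoc p < α) from each other route; *goal-dependent* — routes 2
and 3 each differ from routes 1 and 4 and not from each other; otherwise
unclassified. If several routes qualify simultaneously the route whose
marginal mean deviates most is taken (a tie-break the definitions leave
open). Population counts feed `population_pattern_tests()`: Pearson
goodness-of-fit of the five pattern counts against uniform, and
centre-preferring (route 2 + route 3 + goal) versus outer (1 + 4) against
50/50.

## Ensemble decoding

Per session and sector (start box and central stem — the segments common to
all routes), `trial_population_vectors()` assembles the trial × cell rate
matrix (ensembles need ≥ 6 cells). Each trial is compared by cosine
similarity with four route-average goal vectors computed *leaving that
trial out* of its own route's average, and matched to the arg-max (ties
broken uniformly at random under the session seed). The null shuffles, for
each neuron independently, the identity of the route — but not of the
neuron — among its four goal-vector entries, and re-decodes.

A single strongly route-coded ensemble makes the shuffled diagonal
percentage bimodal (whichever goal vector inherits a route's signature
cells wins that entire row, each with probability ≈ 1/4), so per-session
percentile p-values bottom out near 0.1. The original analysis pools match
proportions over all sessions before taking the percentile, which is what
`decode_sessions()` implements; the validation suite pools 12 simulated
sessions (scaled down from the 25 recorded ones). p-values are
$1 - \hat F(\text{observed})$ with $\hat F$ an Epanechnikov-kernel smoothed
CDF of the shuffle distribution; the bandwidth is Silverman's rule on the
shuffle sample (the original used its tooling's default; Silverman is
declared and configurable). `within_block_trend()` checks stationarity:
Spearman correlations of within-block trial position (truncated at 12, the
mean block length being 12.5) against correct-match indicator and
similarity.

## Goal-box similarity

`boxroute_vectors()` pools, over all cells (and sessions, concatenating
cell-session entries), the mean firing rate in each route's destination box
from box entry to trial end — whether reward consumption should be
truncated is unstated, so the full window is used. The six Spearman
correlations among {Left@R1, Centre@R2, Centre@R3, Right@R4} are tested
against a null that, per cell, draws one of the three rates belonging to
the *other* labels (route identity shuffled, cell order preserved; a random
single draw rather than with-replacement resampling, the reading adopted
for the unstated detail), with the same smoothed-CDF percentile p. The
route-invariant centre-box generator contract makes Centre@R2–Centre@R3 the
only pair that should beat chance.

## Behavioural scoring

`score_blocks()` splits each block at its first correct trial: errors and
mean trial times before (search) and after (confusions). An error is entry
into an unrewarded goal box; runs stopped at the centre barrier count as
errors toward the blocked route. `confusion_pairs()` groups
post-identification errors into the six unordered {chosen, rewarded} route
pairs; the accounting identity (pair counts sum to total post errors) is
enforced by construction and tested.

## Numerical choices and problem sizes

* Rate-map kernels are evaluated exactly (no truncation radius); the map is
  chunked over bins to bound memory.
* The permutation F uses one QR decomposition per design and matrix
  products per shuffle, so k = 5000 per cell is cheap.
* Stage seeds are derived deterministically from a single session seed;
  identical seeds reproduce trajectories, spike trains, decodes and
  shuffles bit-for-bit.
* The validation suite uses sessions of 4 blocks × 11 post-identification
  trials (~11 trials/route, start-box dwell 6–9 s), 1000 cells for type-I
  calibration (permutation at k = 1000), 200 cells for pattern recovery,
  12 pooled 12-cell sessions with 2000 shuffles for decoding, and 60 cells
  with 2000 shuffles for the goal-box analysis — sizes chosen so the whole
  suite runs in minutes while leaving Monte-Carlo error well inside the
  asserted margins. Function defaults keep the published sizes
  (k = 5000, 10000 shuffles).

## Known limitations

* The ranked ANCOVA's residual ANOVA does not adjust its denominator df for
  the prior rank regression; under the null generator its size is ≈ 0.043
  at α = 0.05 — slightly conservative, matching its standing as the
  primary, cautious test.
* Percentile p-values inherit the shuffle resolution; reported zeros mean
  "beyond every shuffle", bounded below by ~1/n_shuffles.
* The simulator's behavioural model is a caricature (win-stay belief plus
  uniform elimination search); it reproduces error counts and confusion
  structure, not trial-by-trial rat behaviour.
* Waveform widths are not simulated, so the width criterion only binds on
  real feature data.

## A minimal end-to-end run

```{r example, eval = FALSE}
specs <- route_coded_population(n_cells = 8, seed = 64)
sess <- simulate_population_session(session_config(seed = 64), specs)
out <- run_pipeline(sess, out_dir = tempfile(), n_shuffles = 500, seed = 9)
out$pattern_counts        # route-specific labels dominate
out$decoding$start_box    # near-perfect diagonal match matrix
```
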