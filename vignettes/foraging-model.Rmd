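---
title: "The working-memory foraging model: simulation, summaries, and grid-search fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The working-memory foraging model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oculoforage)
```

## The task and the model

In the oculomotor foraging task a subject faces 15 visually identical
objects placed on a 7 x 11 grid with 4 degrees of visual angle between
adjacent sites (76 candidate sites once the site nearest the fixation
point is excluded). One object hides a reward; the subject inspects
objects by sequential saccades under a 6-s limit. Efficient search
requires remembering which objects were already inspected — revisits
(recursive saccades) are the behavioral signature of working-memory
failure.

The foraging agent formalizes this with three parameters:

* **memory capacity** `C` (1–15): the maximal number of inspected
  objects held in the store at once;
* **memory decay** `D` (1–`C`): when the store is full, the evicted
  item is drawn uniformly among the `D` oldest entries. `D = 1` is
  strict first-in-first-out forgetting; `D = C` is uniformly random
  forgetting;
* **utility rate** `U` (0–1): the probability that a choice consults
  the store at all. With probability `U` the next object is drawn
  uniformly among objects neither remembered nor currently fixated
  (exploitation); otherwise uniformly among all objects except the
  current one (exploration).

A trial draws the target uniformly, lets the agent choose until the
target is found or a saccade cap is reached, and registers every
visited non-target object in the store.

Three conventions had to be fixed where the model definition is silent:

* **Re-registration** of an already-remembered object refreshes its
  recency rather than duplicating it (a duplicate would leak capacity);
  `update_memory(refresh = "ignore")` exposes the alternative.
* **The first choice** of a trial has no current object — gaze starts
  on the fixation point — so all 15 objects are candidates; every
  later choice excludes the currently fixated object in both modes.
* **Eviction precedes insertion**, and the evicted slot is drawn among
  the `D` oldest entries of the pre-insertion store. A found target
  terminates the trial before any memory update.

Two engines implement the agent: an interpreted reference
(`simulate_trial`, built from the exported `choose_next` and
`update_memory`) and a compiled core used by `simulate_agent` and the
grid sweep. Both map every random draw through a single uniform
deviate in the same order, so under the same seed they produce
bit-identical sessions — the equivalence is asserted in the tests, and
an exhaustive path-enumeration oracle checks the compiled engine's
outcome probabilities on a 3-object toy problem.

## Summary distributions

Fitting never sees raw choice sequences; it sees three 25-bin
distributions (`summarize_trials`):

1. the proportion of revisits at each saccade ordinal 1–25,
   conditioned on trials surviving to that ordinal (an `"all"-trials`
   denominator is available; conditioning avoids deflating late bins
   through trial attrition);
2. the histogram of revisit distances, measured as the difference of
   saccade indices (an A-B-A pattern has distance 2 — the same events
   counted as "intervening saccades" would read 1; model and data
   share the convention, so the choice only relabels the axis);
3. the histogram of per-trial saccade counts.

Mass beyond bin 25 clips into bin 25 rather than being dropped, and
each vector is sum-normalized. A component with no events (e.g. no
revisits under a perfect agent) stays all-zero and is flagged; it
still contributes its 25 zero bins to the concatenated 75-bin fitting
vector, keeping the geometry fixed. Censored (failed) trials are
included in all summaries.

## Grid-search fitting

The parameter space is exhaustively enumerated: capacity 1–15, decay
1–capacity, utility 0–1 in steps of 0.02 — 6,120 combinations
(`parameter_grid()`). Each grid point is simulated once
(`build_grid_cache`), its summary triplet stored; because the
simulated summaries do not depend on the data, one cache serves every
fit, bootstrap resample, and time-course window. Simulation noise is
frozen under a recorded seed, so fits are deterministic; rebuilding
the cache with the same metadata reproduces it exactly.

Goodness of fit between the observed vector `M` and a simulated vector
`S` is the coefficient of determination

$$\mathrm{CD} = 1 - \frac{\sum_b (M_b - S_b)^2}{\sum_b (M_b - \overline{S})^2},$$

with $\overline{S}$ the grand mean of the *simulated* vector — as the
statistic is defined for this analysis. A conventional
$R^2$-style centering on `M` is available (`center = "observed"`) but
is not the default. `CD = 1` iff `M = S`; values can be negative. The
argmax over the grid is the fit; ties break toward the earliest grid
row (lowest capacity, then decay, then utility). Fits with best CD
below 0.7 are flagged unreliable and their parameters should not be
interpreted — sliding-window analyses propagate this flag instead of
reporting parameters.

Two cautions from the package's own simulations, both visible in the
test suite:

* With the full 5,000-trial-per-point grid, 5,000 observed trials at
  (10, 2, 0.90) are recovered within capacity ±1 and utility ±0.04 in
  20/20 seeds (best CD ≥ 0.98). With a 500-trial-per-point cache the
  utility argmax acquires a noise floor of one to three 0.02-grid
  steps (the rarer the revisits, the noisier a point's summary, and
  that variance enters the CD numerator), and roughly one seed in
  twenty lands 0.06 from the generating value. The cache size is the
  accuracy dial; 500 is used in the tests to keep the suite fast.
* Decay has the weakest behavioral signature of the three parameters;
  recovery tolerances for it are necessarily loose (about half the
  capacity).

`bootstrap_intervals` resamples trials with replacement, refits each
resample against the same cache, and reports the middle 95% of the
resampled parameters; a post-injection estimate outside the baseline
interval is declared a significant modulation. `sliding_window_fit`
pools trials across sessions per 10-min window in 5-min steps
(pooling precedes fitting, matching how multi-session conditions are
combined) and fits each window. `parameter_pair_distance` is the
squared sum of normalized parameter differences used to compare
within- against across-subject session dispersion; the default
normalization in the examples is the per-parameter standard deviation
across the sessions compared, since no scale is canonical.

## The synthetic-data generator

`generate_session` is the package's stand-in for recorded sessions: it
drives the agent through fresh stimulus arrays with per-trial wall
clocks (fixation 500–1000 ms, ~220-ms intersaccadic intervals, 200-ms
reward delay, 800-ms intertrial interval), censors trials whose
cumulative search time exceeds the 6-s limit, and caps trials at 25
saccades, matching the summary support. `drug_profile` emulates a
pharmacological intervention phenomenologically: a linear ramp to peak
effect within the onset time (default 10 min), then exponential
recovery (default half-life 20 min); at peak, each model parameter is
multiplied by its effect scale, and kinematic effects (velocity scale,
postsaccadic drift, intersaccadic-interval inflation) follow the same
time course. The generator emulates the statistical structure the
analyses assume — it does not model spatial choice biases (real
subjects prefer neighboring objects; the agent treats objects as
exchangeable), pharmacokinetics, or reaction-time structure beyond the
interval distribution. Passing tests therefore demonstrate that the
pipeline recovers what the model family can express, not that the
model captures every regularity of real foraging data.

`generate_eye_trace` renders a trial as a 1-kHz two-channel gaze
trace: minimum-jerk saccade profiles whose peak velocities follow the
main-sequence relation $\dot{E} = \dot{E}_{max}(1 - e^{\tau \cdot Amp})$
(duration `1.875·Amp/v_peak`), optional exponential postsaccadic drift
(30-ms time constant, parameterized by its 100-ms displacement — the
measurement window of the drift statistic), and optional Gaussian
position noise. Fixation dwells are floored at 120 ms so every
genuine inspection exceeds the 100-ms registration criterion.

## Oculomotor analyses

`detect_saccades` applies conjunctive criteria per candidate event:
smoothed velocity above 70 deg/s, peak acceleration above
1000 deg/s^2, net displacement above 2 degrees. Differentiation of
1-kHz position at these noise levels requires smoothing; a 2nd-order,
21-ms Savitzky–Golay filter precedes central differences (both
parameters are arguments). Event boundaries are the 10-deg/s velocity
crossings extended down the monotone velocity slope to its foot;
epochs closer than 20 ms merge, since the 2-degree displacement
criterion against 4-degree object spacing means corrective saccades
can otherwise fragment one inspection. On noiseless synthetic traces
the detector recovers implanted event counts exactly and onsets within
±5 ms (offsets sit on the slow minimum-jerk tail and are a few ms
early).

`register_choices` (2-degree radius, >100-ms dwell),
`postsaccadic_drift` (displacement over the 100 ms after offset,
flagged missing when the window is truncated or crosses the next
onset), `intersaccadic_intervals`, `fit_main_sequence` (nonlinear
least squares started at `e_max = max(v)`, `tau = -2/median(amp)`,
bounded to `e_max > 0`, `tau < 0`; at least 5 saccades spanning more
than 5 degrees), `saccade_gain` (target-projected amplitude over
target distance), and `exclude_trial` (any search-epoch sample outside
the 33 x 48-degree virtual window) complete the battery.

## Problem sizes and numerical choices

The test suite runs at deliberately reduced scale: 500 simulated
trials per grid point (the full-scale analyses use 5,000), 200
bootstrap resamples (vs 1,000), 50-replicate coverage studies, and a
100,000-trial enumeration check. These sizes were chosen so the whole
suite completes on a single CPU in minutes while keeping Monte-Carlo
error well inside the asserted tolerances, except where noted above
for the 500-trial cache. Degenerate inputs are contracts, not
surprises: an all-constant reference vector makes the CD denominator
zero and errors; empty sliding windows are flagged and skipped; a
single-resample bootstrap returns a degenerate interval; zero-flagged
summary components never raise.

## Known limitations

* The agent is object-identity-only: no spatial layout, no neighbor
  preference, no reaction-time model. Parameter estimates from real
  data inherit whatever bias that omission induces.
* Utility and capacity produce qualitatively similar distortions of
  the summary distributions; they are identifiable jointly but their
  estimates correlate in small samples.
* The drug profile is phenomenological — a ramp plus exponential
  recovery — and makes no pharmacological claims.
* The 0.02 utility grid bounds the resolution of any utility
  statement; differences below one grid step are not meaningful.
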