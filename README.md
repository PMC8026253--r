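# oculoforage

Quantifying working memory from oculomotor foraging behavior.

In an oculomotor foraging task a subject searches 15 visually
identical on-screen objects for a hidden reward target by sequential
saccades, under a 6-s limit. Because the objects carry no visual
marks, efficient search depends entirely on short-term memory for the
objects already inspected; saccades back to an inspected object
(*revisits*) are the behavioral signature of working-memory failure.
This package implements a stochastic foraging agent with three
working-memory parameters, and the full analysis pipeline that
estimates those parameters from behavior:

* **memory capacity** `C` — how many inspected objects the store
  holds (1–15);
* **memory decay** `D` — which stored item is forgotten when the
  store is full: the evicted item is uniform among the `D` oldest
  (`D = 1`: strictly the oldest; `D = C`: any item);
* **utility rate** `U` — the probability that a choice consults the
  store at all: with probability `U` the next object is uniform among
  objects neither remembered nor currently fixated, otherwise uniform
  among all non-current objects.

Behavior is summarized by three 25-bin distributions (revisit
proportion per saccade ordinal, revisit distance in saccade indices,
per-trial saccade count), concatenated into a 75-bin vector `M`.
Fitting is an exhaustive Monte-Carlo grid search over all 6,120
parameter combinations (capacity 1–15, decay 1–capacity, utility
0–1 in 0.02 steps), maximizing the coefficient of determination
against each combination's simulated vector `S`:

```
CD = 1 − Σ_b (M_b − S_b)² / Σ_b (M_b − mean(S))²
```

Fits with best CD < 0.7 are flagged unreliable. Around the fit sit
bootstrap significance intervals (middle 95% of resampled refits),
sliding-window time courses (10-min windows, 5-min steps) for
pharmacological experiments, a session-dispersion statistic, and the
accompanying oculomotor battery: saccade detection on 1-kHz gaze
traces (70 deg/s velocity, 1000 deg/s² acceleration, 2-degree
displacement criteria), choice registration, postsaccadic drift,
intersaccadic intervals, main-sequence fitting
`v = e_max (1 − exp(τ·Amp))`, target-projected saccade gain, and
virtual-window trial exclusion. A synthetic-data generator produces
complete sessions (task geometry: 15 objects drawn per trial from the
76 candidate sites of a 7 × 11, 4-degree grid) and eye traces with
main-sequence kinematics, so the whole pipeline is testable without
recorded data.

## Worked example

```r
library(oculoforage)
set.seed(1)

agent   <- forage_params(capacity = 10, decay = 2, utility = 0.9)
session <- generate_session(agent, n_trials = 500)
session
#> <forage_session> subject synthetic, condition none, 500 trials, 30.9 min

obs <- summarize_trials(session_outcomes(session))
obs
#> <summary_triplet> 500 trials, 25 bins; zero-flagged: none

cache <- build_grid_cache(n_sim_trials = 500, seed = 42)  # ~13 s, reusable
fit   <- fit_forage_model(obs, cache)
fit
#> <forage_fit> capacity 11, decay 3, utility 0.88; CD = 0.894 (reliable)

boot <- bootstrap_intervals(session_outcomes(session), cache, n_boot = 200)
boot
#> <forage_bootstrap> 200 resamples, 95% intervals
#> # A tibble: 3 × 4
#>   parameter point lower upper
#>   <chr>     <dbl> <dbl> <dbl>
#> 1 capacity  11    10    11
#> 2 decay      3     2     3
#> 3 utility    0.88  0.82  0.92
```

The fitted capacity/utility land one grid step from the generating
values — about the resolution a 500-trial session supports — and the
bootstrap intervals cover the generating parameters (capacity 10,
utility 0.90). The `CD = 0.894` line says the best grid point explains
~89% of the variance of the observed 75-bin summary around the
simulated reference mean; `reliable` means it clears the 0.7
threshold below which parameters should not be interpreted.
`sliding_window_fit()` applies the same fit per post-injection time
window, and `generate_eye_trace()` / `detect_saccades()` /
`fit_main_sequence()` cover the kinematic side. The methods vignette
(`vignettes/foraging-model.Rmd`) documents the model, conventions,
and numerical choices; `inst/scripts/forage` is a thin command-line
wrapper (`generate`, `summarize`, `fit`, `pipeline`).

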