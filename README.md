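# protrack

Tools to study **manual digitization of markerless videos**: how fast
and how accurately can a point of interest be tracked by clicking it on
every frame (*frame-wise tracking*) versus following it with the cursor
while the video plays (*progressive tracking*)?

The package targets researchers in biomechanics, functional morphology
and behavioral science who digitize kinematic landmarks by hand, and
anyone building or evaluating tracking software. It provides the full
evaluation loop without human subjects:

* **Synthetic benchmark videos** — a 13 px blurred point moving with
  random 2D acceleration (speeds 0–22.8 px/frame) across an
  800 × 800 px frame, with exact ground truth (`video_config()`,
  `simulate_trajectory()`, `render_frame()`, `write_video()`).
* **A tracking session engine** — both modes over a playback clock with
  rewind correction, zoom/pan, and an input abstraction usable by
  humans or simulated agents (`session_new()`, `progressive_advance()`,
  `framewise_click()`, `rewind()`).
* **Simulated operators** — a first-order pursuit agent (velocity-
  dependent lag) and a Fitts-law click agent (velocity-dependent
  cadence with a plateau) standing in for human users and input
  devices (`pursuit_agent()`, `click_agent()`, `run_trial()`).
* **Performance metrics** — speed `S = 1/Δt` (fps), accuracy
  `A = 1/(1+d)` (px⁻¹, `d` the Euclidean error), paired per-frame
  differences, and repeated-trial precision `P = 1/(1+σ)`
  (`frame_metrics()`, `paired_deltas()`, `filter_valid()`,
  `track_precision()`).
* **A piecewise Bayesian changepoint model** — the core statistic:

  ```
  ΔS ~ Normal( b + c (V − V_crit) · [V ≤ V_crit],  ε )
  ΔA ~ Normal( b + c (V − V_crit) · [V ≥ V_crit],  ε )
  ```

  with plateau `b`, slope `c` and critical point velocity `V_crit`
  estimated per user × device by MCMC, and model variants without the
  breakpoint, user or device term compared by WAIC and PSIS-LOO
  (`fit_piecewise()`, `compare_piecewise()`, `waic()`, `psis_loo()`).

Everything is deterministic given seeds, tibble-first, and pipe-
friendly; fitted models support `tidy()`, `glance()` and `autoplot()`.

## Worked example

Simulate a reduced benchmark (2 videos × 500 frames, 2 users × 2
devices × 2 modes), summarize the metrics, and fit the speed model:

```r
library(protrack)
library(dplyr)

res <- run_benchmark(benchmark_manifest(n_videos = 2, n_frames = 500, seed = 1))
res
#> <benchmark_result> 2 videos x 500 frames, 16 trials, 8000 tracked frames
#>   valid frames: 7984; paired frames: 3992

summarize_metrics(res$metrics_valid, by = "mode") |> filter(mode != "pooled")
#>   metric     n  mean median    q25    q75 mode
#> 1 S       3992 1.44   1.45  1.18    1.80  frame_wise
#> 2 A       3992 0.535  0.518 0.431   0.627 frame_wise
#> 3 d       3992 1.00   0.931 0.594   1.32  frame_wise
#> 4 S       3992 3.23   3.23  3.23    3.23  progressive
#> 5 A       3992 0.179  0.150 0.0861  0.214 progressive
#> 6 d       3992 6.84   5.68  3.66   10.6   progressive
```

Progressive tracking runs at the fixed playback speed of 3.23 fps —
more than twice the mean frame-wise speed (1.44 fps) — while frame-wise
tracking is the more accurate mode (mean error 1.0 px vs 6.8 px for
these agent settings). The changepoint model quantifies how the speed
difference depends on point velocity:

```r
fit <- fit_piecewise(res$deltas, outcome = "delta_S", variant = "full",
                     chains = 2, iter = 1000, warmup = 1000, seed = 1)
tidy(fit)
#>    term    group    estimate std.error conf.low conf.high  rhat   ess
#>  1 b       U1:mouse  -2.04    0.00144   -2.04     -2.04    1.00  1121.
#>  2 b       U1:pen    -1.42    0.00137   -1.42     -1.41    1.00  1209.
#>  ...
#> 10 v_crit  U1:mouse  11.0     0.165     10.7      11.2     1.03   150.
#> 11 v_crit  U1:pen     9.96    0.0633     9.86     10.1     1.02    99.4
#>  ...
```

`ΔS` is negative everywhere (frame-wise is slower), shrinks as `V`
falls below each group's `V_crit` (≈ 10–11 px/frame here), and the pen
groups plateau at a smaller deficit than the mouse groups — the
structure the model is built to detect. `autoplot(fit)` overlays the
posterior mean curves and 89% bands on the data;
`compare_piecewise(res$deltas, "delta_S")` ranks the model against the
variants without `V_crit`, user or device terms.

Raw tracking tables from other tools (or published supplements) can be
ingested with `read_supplementary_tables()`, which sniffs the delimiter
and maps flexible column layouts onto the package schema so the same
metric pipeline applies.

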