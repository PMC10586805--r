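# larvahab

Analysis pipeline for the behavioral habituation of crawling *Drosophila*
larvae exposed to pulsed vertical vibration. The package is aimed at
computational ethologists and behavioral neuroscientists who work with
tracked larva trajectories and want reproducible, tested implementations
of the standard analyses for this assay:

* **behavior classification** — continuation / pause / turn / reverse
  crawl, assigned per animal per stimulus pulse from kinematic time
  series (speed-based stop detection, a 30° heading-change rule, and a
  head-vector·velocity dot-product criterion for backward crawling);
* **population response fractions**
  `F_ACTION = N_ACTION / N` (with `F_CONT + F_PAUSE + F_TURN + F_REV = 1`
  and `F_STOP = F_PAUSE + F_TURN + F_REV`), condition grids over
  `(f, Γ)` stimulus space, and two-sided Fisher exact comparisons;
* **individual transition matrices** between responses to pulse `n` and
  pulse `n + k`, quantifying the one-way character of habituation
  (reversals are repeated or abandoned, essentially never re-entered);
* **habituation kinetics** — exponential fits of
  `y0 + A·exp(−t/τ)` with the offset fixed at the baseline:
  de-sensitization `F_REV(t) = F_0·exp(−t/τ_des)` under sustained
  vibration, re-sensitization `F_REV(T_OFF) = F_0·(1 − exp(−T_OFF/τ_res))`
  during stimulus gaps, and the collapse of `τ_res(n)` to under a second
  after repeated pulses; uncertainties from a 1000-resample parametric
  bootstrap (Gaussian resampling at each point's SEM), and fit
  comparisons with a resample-count-invariant z statistic;
* an **LTI impulse-response predictor** `R[t] = Σ S[τ]·h[t−τ]` whose
  failure under continuous stimulation demonstrates that the response is
  adaptive, not linear;
* a **capacitor-switch circuit analog**: charge packets `Q1 = C1·V`
  accumulate on a leaky reservoir (`Q2` decaying with `R·C2`) and the
  event probability follows `F = F0·exp(−Q2)`;
* a **seeded synthetic-data generator** producing response records,
  binned count series and geometric trajectories with this statistical
  structure, so every stage is testable without the original recordings.

Stimuli are described by frequency `f` (Hz), dimensionless peak
acceleration `Γ = Aω²/g`, pulse duration `T_ON`, gap `T_OFF` and pulse
count. Default generator constants (baselines 0.03/0.24, naive reversal
fraction 0.55, wild-type `τ_des = 18.9 s`, `τ_res = 5.3 s`, and the
*rut*/*dnc*/*cam0* strain presets) are documented in
`vignettes/larvahab-methods.Rmd`, together with every tunable threshold
and the design decisions behind the estimators.

## Worked example

Simulate a standard pulse-train experiment (f = 500 Hz, Γ = 2,
T_ON = 10 s, T_OFF = 20 s, 10 pulses, 100 larvae), then run the core
analyses:

```r
library(larvahab)

protocol <- stimulus_protocol(500, 2, t_on = 10, t_off = 20, n_pulses = 10)
cfg <- generator_config(n_larvae = 100, seed = 42)

rec <- generate_response_records(cfg, protocol)
head(fractions_by_pulse(rec), 4)
#>   pulse_n   n f_cont f_pause f_turn f_rev f_stop
#> 1       0 100   0.10    0.12   0.29  0.49   0.90
#> 2       1 100   0.30    0.10   0.16  0.44   0.70
#> 3       2 100   0.42    0.10   0.11  0.37   0.58
#> 4       3 100   0.49    0.10   0.14  0.27   0.51

transition_matrix(rec, lag = 1)
#> transition_matrix (lag 1, 900 transitions), row percentages:
#>        to
#> from     CONT PAUSE TURN  REV
#>   CONT  100.0   0.0  0.0  0.0
#>   PAUSE  58.6  34.3  7.1  0.0
#>   TURN   36.6  23.2 40.2  0.0
#>   REV     2.8   6.5  6.9 83.8
```

Half the animals reverse-crawl at the first pulse and the reversal
fraction habituates across the train; at the individual level reversals
repeat 83.8% of the time here (the generating persistence is 85%) and the
REV column is empty off the diagonal — habituation is one-way.

```r
desensitization_experiment(cfg, n_boot = 1000)$fit
#> fit_result: tau = 19.305 +/- 0.802 s (A = 0.521, y0 = 0.030, 1000 resamples)

resensitization_experiment(cfg, n_boot = 1000)$fits[["n=1"]]
#> fit_result: tau = 5.930 +/- 0.727 s (A = 0.860, y0 = 0.000, 1000 resamples)
```

The continuous-vibration fit recovers the generating de-sensitization
constant (18.9 s) within its bootstrap uncertainty, and the
`T_OFF`-family ratio analysis recovers the first re-sensitization
constant (5.3 s) within its. The circuit analog's per-switch peaks
decline toward saturation:

```r
round(peak_series(circuit_params(), 5), 4)
#> [1] 0.1657 0.0613 0.0269 0.0136 0.0077
```

`run_pipeline()` ties the stages into a deterministic end-to-end run with
a checksummed manifest, and `pipeline_report()` renders a summary whose
numbers are read back from the artifacts themselves.

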