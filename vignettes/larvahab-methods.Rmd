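---
title: "Models and methods: vibration habituation in crawling larvae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: vibration habituation in crawling larvae}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvahab)
```

## The system and the measurements

Crawling *Drosophila* larvae respond to pulsed vertical vibration with a
small, discrete repertoire: they continue crawling (CONT), pause and resume
in roughly the same direction (PAUSE), stop and head off in a new direction
(TURN), or crawl backward (REV) — in ascending order of avoidance strength.
A stimulus is described by four numbers: the vibration frequency $f$ (Hz),
the dimensionless peak acceleration $\Gamma = A\omega^2/g$ (with
$\omega = 2\pi f$ and $A$ the displacement amplitude), the pulse duration
$T_{ON}$ and the inter-pulse gap $T_{OFF}$; the period is
$T = T_{ON} + T_{OFF}$ and pulses are indexed $n = 0, 1, 2, \dots$

The pipeline classifies one response per animal per pulse from tracked
trajectories, aggregates them into population fractions
$$F_{n,\mathrm{ACTION}} = N_\mathrm{ACTION}/N, \qquad
  F_{CONT}+F_{PAUSE}+F_{TURN}+F_{REV}=1,$$
builds individual-level transition matrices between consecutive (or
lag-$k$) pulses, and characterizes habituation with three quantities:

* **de-sensitization** during sustained stimulation,
  $F_{REV}(t) = F_{0,REV}\, e^{-t/\tau_{des}}$;
* **re-sensitization** while the stimulus is off,
  $F_{REV}(T_{OFF}) = F_{0,REV}\,(1 - e^{-T_{OFF}/\tau_{res}})$;
* the **acceleration of re-sensitization** with pulse number, captured by a
  pulse-indexed schedule $\tau_{res}(n)$ that collapses below one second
  after the first two gaps.

A pulse-train prediction combines these
(`predict_pulse_train()`): during the ON window of pulse $n$,
$F_{REV}(t) = F_{0,REV}\, r_n\, e^{-(t-nT)/\tau_{des}}$ with $r_0 = 1$ and
$r_n = 1 - e^{-T_{OFF}/\tau_{res}(n-1)}$, and zero while the stimulus is
off (it is an event probability, not a state). A linear time-invariant
(LTI) convolution predictor built from the measured impulse response
(`extract_irf()`, `lti_predict()`) is included precisely because it fails:
under continuous stimulation the animals return to baseline while the
convolution stays elevated, which is the core evidence that the response
is adaptive rather than linear. Finally, a capacitor-switch circuit
(`simulate_charge()`, `event_fraction()`) gives a physical analog: each
switch closing dumps a fixed charge packet $Q_1 = C_1 V$ onto a reservoir
capacitor $C_2$ that leaks through $R$,
$$Q_2(t) = \sum_n C_1 V\, \theta(t - nT)\, e^{-(t-nT)/RC_2}, \qquad
  F_{event}(t) = F_0\, e^{-Q_2(t)},$$
so accumulated charge plays the role of accumulated habituation.

## The synthetic-data generator

The package replaces the study's raw recordings with a seeded generator
whose defaults are the study's printed constants:

| parameter | default | meaning |
|---|---|---|
| `baseline_rev` | 0.03 | spontaneous reversal fraction per window |
| `baseline_stop` | 0.24 | spontaneous fraction showing any avoidance |
| `f0_rev` | 0.55 | naive reversal fraction at $f=500$ Hz, $\Gamma=2$ |
| `f0_stop` | 0.90 | naive stop fraction at the same intensity |
| `tau_des` | 18.9 s (wild type) | de-sensitization time constant |
| `tau_res0` | 5.3 s (wild type) | re-sensitization after the first pulses |
| `tau_res_late` | 0.8 s | re-sensitization after the first two gaps |
| REV repeat | 0.85 | lag-1 reversal persistence |
| pause/turn split | 0.35/0.65 | share of non-REV stops |

Strain presets (`strain_preset()`) carry
$(\tau_{des}, \tau_{res})$ = (18.9, 5.3) for the wild type, (5.2, 3.6) for
*rut*, (14.3, 9.8) for *dnc* and (25.6, 6.5) for *cam0*. `f0_stop = 0.90`
is the package's own choice (nearly all animals interrupt crawling at the
strong reference intensity); the pause/turn split and the non-REV rows of
the transition kernel are plumbing defaults, configurable and without
printed counterparts.

### Sequencing model: reconciling marginals with one-way habituation

Two constraints on individual response sequences cannot both be taken
literally: (i) the per-pulse reversal marginal implied by the pulse-train
model, which for $T_{OFF} = 20$ s barely declines across a train, and
(ii) the individual-level structure — reversals repeat with probability
0.85 and are *never* re-entered from a weaker behavior (one-way
habituation). A population satisfying (ii) necessarily has marginals
declining by the repeat factor. The generator gives the individual-level
structure precedence:

$$P(\mathrm{REV}_n \mid \mathrm{REV}_{n-1}) = \rho\,
  \bigl(1 - e^{-T_{OFF}/\tau_{res}(n-1)}\bigr), \qquad
  P(\mathrm{REV}_n \mid \text{non-REV}_{n-1}) = 0,$$

with $\rho = 0.85$. The marginal is then
$F_{0,REV}\,\rho^n \prod_{k\le n} r_k$: peaks decline geometrically (as
observed empirically), the recovery ratio
$F_{n,REV}/F_{n-1,REV} = \rho\, r_n$ retains the full $T_{OFF}$
dependence that identifies $\tau_{res}$, and the one-way property is
exact. The residual per-pulse factor $\rho$ is the generator's rendering
of the additional layer of habituation that persists even when the OFF
gap allows full $\tau_{res}$ recovery. Weaker behaviors follow a
stationary kernel in which continuation is absorbing, so the lag-5 matrix
has zero entries into REV and zero exits from CONT. Below the sensitivity
threshold in $(f, \Gamma)$ space (defaults $\Gamma \ge 1$, $f \ge 100$
Hz) all windows are independent baseline draws; spontaneous reversals are
therefore exempt from the one-way constraint, which describes stimulated
sequences.

The count-series generator draws per-bin binomial counts around a
deterministic expectation: each pulse onset resets the reversal
expectation to that pulse's peak, after which it relaxes toward the
baseline with $\tau_{des}$ through ON window and OFF gap alike — so a 1-s
near-delta burst produces the slow (~15–20 s) return to baseline that the
impulse-response experiments show.

Geometric trajectories (15 frames/s) realize label scripts as piecewise
paths: runs at 0.5 mm/s; pauses/turns as full stops with resumption
heading changes drawn from $[0^\circ, 30^\circ)$ / $(30^\circ,
150^\circ]$; reversals as a stop followed by a backward bout in which the
head-orientation vector opposes the velocity. What the generator does
*not* emulate: body contours and peristalsis, collisions, tracking noise
and dropouts, hunching/rolling/burrowing, the transient stop-fraction dip
after stimulus offset ("relief"), and any spatial non-uniformity of
$\Gamma$ across the arena. Passing round-trip and recovery tests
therefore validates the analysis logic, not robustness to real tracker
artifacts.

## Classifier choices

The stop rule ("drops significantly in speed") is unquantified in
qualitative descriptions of such assays; the package stops when the
5-frame-smoothed speed falls below 0.2 x the animal's median smoothed
speed (absolute floor 0.05 mm/s for near-stationary records) for at least
0.5 s. Headings are averaged over 1 s before and after the stop, with a
0.2 s margin (one smoothing half-width) excluded on both sides so frames
smeared across the stop boundary do not bias the angle; $\Delta\theta$
exactly at the 30 degree threshold resolves to the stronger behavior
(TURN). REV requires the head-velocity dot product to stay negative for
at least 0.5 s during or within 2 s after a stop. Pulse responses use a
3-s window with the mid-action rule: an ongoing action counts, forward
crawling that transitions into an action is relabeled, and the strongest
resolving action (REV > TURN > PAUSE) wins; stops that never resolve are
UNRESOLVED and excluded from $N$, as are windows the trajectory does not
span. Widening the window to 5 s changes aggregate fractions by well
under 0.05 on synthetic data.

## Fitting and uncertainty

Habituation fits use $y_0 + A e^{-t/\tau}$ with $y_0$ fixed at the
baseline, bounded Levenberg–Marquardt least squares
($\tau \in [0.1, 300]$ s, $A \in [0, 1]$, start $\tau = 10$ s,
$A = F(0) - y_0$). For binned count data the fit is iteratively
reweighted (two passes) with model-based binomial weights
$n/\hat p(1-\hat p)$: data-based weights over-weight zero-count baseline
bins and bias $\tau$ low, while model-based weights approximate the
binomial maximum-likelihood estimator (unbiased, ~30% tighter than
unweighted least squares in calibration runs). Uncertainty follows the
parametric bootstrap: each point is resampled from a Gaussian centered on
its value with its SEM as width (negative resamples clipped to zero), the
fit repeated 1000 times with the point fit's weights frozen, and the SD
of the resampled $\tau$ reported. Fits are compared with
$z = \Delta\bar\tau / \sqrt{s_A^2 + s_B^2}$ on the bootstrap sets — the
two-sample $t$ statistic rescaled by $1/\sqrt{n_{boot}}$ so that the
number of resamples cannot manufacture significance.

### Recovery-ratio analysis

$\tau_{res}(n-1)$ is estimated from families of experiments sharing
$(f, \Gamma, T_{ON} = 30\,\mathrm{s})$ and varying
$T_{OFF} \in \{0.5, 1, 2, 5, 10, 20, 40\}$ s. Because reversal at pulse
$n$ implies reversal at pulse $n-1$ under one-way habituation, the ratio
is the conditional proportion $k_n/k_{n-1}$ with binomial SEM. The
normalization "accounting for incomplete recovery" is implemented as a
*free plateau*: all pulse curves are fit jointly as
$a\,(1 - e^{-T_{OFF}/\tau_n})$ with a single shared amplitude $a$
(IRLS, model-based weights). A largest-tercile plateau estimator is kept
as an option but is not the default: for slow-recovery strains the
largest $T_{OFF}$ values are not yet on the plateau and the tercile mean
biases $\tau$ low by up to ~20%. Late pulses, whose recovery saturates
within even the smallest $T_{OFF}$, pin $a$ tightly. Since
re-sensitization accelerates only after the second pulse, the first two
recovery curves share one slow constant by default (`tie_slow = 2`),
which sharpens the first-re-sensitization estimate without changing its
meaning; set `tie_slow = 1` for fully per-pulse fits.

### Problem sizes and their statistical floor

Calibration runs (40 seeds per setting) give the sampling spread of each
recovered constant under the default designs:

* $\tau_{des}$, 100 larvae, 120 s of 1-s bins: relative SD 3–6% across
  the four strains, no detectable bias.
* first $\tau_{res}$, 100 larvae per $T_{OFF}$ condition: relative SD
  ~9–10%. This is close to the information limit of the design — seven
  binomial ratio points with ~55 reversing animals each — so individual
  runs can deviate by up to ~20%.
* $\tau_{res}$ after the fourth pulse: by then the reversing
  subpopulation has decayed roughly five-fold and only the shortest
  $T_{OFF}$ conditions carry curvature information, so this analysis uses
  a proportionally larger cohort (4000 larvae per condition) and still
  carries ~0.25 s of spread around the 0.8 s generating value.

The bootstrap SDs reproduce these spreads well (e.g. 0.36 vs 0.29 s for
*rut* $\tau_{des}$, 0.82 vs 0.88 s for wild type).

## Circuit model conventions

The charge transfer is instantaneous and always the full packet $C_1 V$,
the $C_2 \gg C_1$ idealization (a warning is issued when $C_2/C_1 < 10$);
the decaying-step summation is implemented literally rather than solving
the exact two-capacitor electrostatics. $\theta(0) = 1$, so $t = nT$
evaluates post-transfer; pre-transfer values are available through a
left-limit flag. Peak event fractions at the switch instants — the only
quantity the analog is meant to reproduce — admit a geometric-series
closed form used as an internal cross-check (agreement to $10^{-10}$ over
1000 switches). By construction the model does not reproduce the decline
of the reversal probability *within* a pulse, only the per-pulse peaks;
`peak_series()` is accordingly the only comparison surface.

## Design notes and known limitations

* The first pulse has no preceding OFF gap; its recovery factor is
  defined as 1 (full naive sensitivity).
* Pause and turn are not given separate habituation constants (none are
  identifiable from the fractions the analysis tracks); stops share the
  reversal's habituation scaling with their own baseline.
* Below-threshold sensitivity is a hard 0/1 gate; the real transition in
  $(f,\Gamma)$ space is sharp but not a step.
* Condition-grid comparisons use two-sided Fisher tests, unadjusted at
  $p < 0.05$; no multiplicity correction is applied.
* Validation relies on parameter recovery from the generator plus
  analytic identities and independent oracles (double-loop convolution,
  hypergeometric enumeration, classifier round trips); none of this
  certifies performance on real tracker output with noise, collisions and
  lost tracks.
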