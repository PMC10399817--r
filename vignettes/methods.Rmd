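---
title: "Vibration-based muscle stiffness and IEMG under venous congestion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vibration-based muscle stiffness and IEMG under venous congestion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myovib)
```

## The problem

Venous congestion (VC) — impaired venous outflow with blood pooling in a
limb, the physiology underlying deep-vein thrombosis — stiffens soft tissue
before the classical clinical signs appear. myovib implements a
myotonometry-style measurement chain for detecting that change from two
skin-mounted sensors on the tibialis anterior: an accelerometer that
captures the tissue's response to a small vibration motor (30 g, strapped
over the muscle), and a surface EMG electrode that captures muscle
electrical activity. The experimental design it models is a staged
occlusion of the common iliac vein in 8 anaesthetized pigs: baseline `T0`,
50 % blockage (`T50-1`, `T50-2`: immediately and one hour later), 100 %
blockage (`T100-1`, `T100-2`), and additional occlusion of the superficial
veins (`TS-1`, `TS-2`), with one leg congested (experimental) and the other
serving as control. At each stage, each leg is recorded for 2 minutes with
the motor running and 30 s without, at 1000 Hz.

Because the original recordings are not publicly available, the package is
built around a seeded synthetic-data generator that reproduces the
*statistical structure* this analysis assumes; every downstream stage is
testable against analytic ground truth.

## The tissue model and the stiffness estimator

Soft tissue under the vibrating unit is modelled as an underdamped
single-degree-of-freedom oscillator: moving tissue mass $M$, stiffness $k$,
viscous damping $c$, natural frequency $f_n = \sqrt{k/M}/2\pi$ and damping
ratio $\zeta = c / (2\sqrt{kM}) < 1$. The stiffness estimator is the
myotonometric ratio
$$ \hat{S} = m \, a_{\max} / \Delta l $$
per 1-second window, where $m$ is the vibrating-unit mass (0.030 kg),
$a_{\max}$ the largest absolute band-passed (75–160 Hz) surface
acceleration in the window, and $\Delta l$ the tissue deformation depth at
the moment of $a_{\max}$, obtained by double-integrating the acceleration.
For any pure oscillation at angular frequency $\omega$ the ratio
$a_{\max}/\Delta l$ equals $\omega^2$ exactly (acceleration and
displacement peak at the same instant with ratio $\omega^2$), so:

* under **continuous** stimulation the motor imposes its own drive
  frequency on the skin and $\hat{S} = m\,\omega_{\text{drive}}^2$
  regardless of the tissue — the estimator is *stiffness-blind*;
* under **impulse** (free-decay) stimulation the tissue rings at its damped
  natural frequency $\omega_d = \omega_n\sqrt{1-\zeta^2}$ and
  $\hat{S} \approx m\,\omega_n^2 = m\,k/M$ — the estimator tracks tissue
  stiffness.

Both modes are provided (`simulate_acc(mode=)`). The default *scenario*
uses impulse mode, because only there does the measured quantity respond to
the congestion-programmed stiffness change; continuous mode is retained as
the analytically trivial case and for the identity test
$\hat{S} = m\omega^2$. This also explains why the analysis band matters:
the default scenarios place $f_n$ at 90 Hz (baseline), inside 75–160 Hz,
and the staged stiffness multipliers (default ramp 1.0 → 1.6 in the
experimental leg) move $f_n$ up to about 114 Hz, still inside the band.

Impulse stimulation is modelled as a myotonometer-like *compress–release*
cycle restarted once per second: the probe recompresses the tissue over
60 ms with a raised-cosine profile (spectral content below 20 Hz, far
outside the analysis band) and releases it from rest; the tissue then rings
down freely. We deliberately avoided the alternative of restarting the
decay with an instantaneous velocity jump: an ideal impulse is spectrally
white, its band-passed response is comparable in amplitude to the ring
itself, and it contaminates the first milliseconds of the decay — exactly
where $a_{\max}$ lives — biasing the estimator by 5–15 %.

**Default damping.** The study gives no tissue damping value. We use
$\zeta = 0.01$: at 90 Hz this means a ring-down time constant of about
180 ms, long compared with the settling time of the 75–160 Hz band-pass
(tens of ms). At $\zeta \gtrsim 0.02$ the ring decays on the same timescale
as the filter transient and *any* band-pass distorts the peak region; we
measured a +14 % bias at $\zeta = 0.02$ versus roughly −1 % at
$\zeta = 0.01$. Light damping is also physically defensible for the small
strain amplitudes involved (sub-millimetre deformations).

## Numerical choices in the stiffness chain

**Zero-phase filtering.** The band-pass is a 4th-order Butterworth applied
forward and backward: zero net phase preserves the temporal alignment of
acceleration and displacement that the ratio estimator requires, and the
magnitude response is the square of the one-pass design. It is realized
spectrally (multiplication by $|H|^2$ on an extended copy of the signal),
which is the forward–backward response exactly.

**Signal extension.** Both filtering and integration need the signal
extended beyond the record ends; whatever the extension implies leaks back
in as an edge transient, and after double integration even a 1 % edge
transient turns into a *velocity step* whose double integral dwarfs the
sub-millimetre displacement signal. We extend by autoregressive (Burg,
order 12, fitted on the outermost 1024 samples) forecasting, which
continues narrow-band content with the right frequency and phase; for a
pure tone the extension is numerically exact, and the first and last
analysis windows stay as accurate as the central ones. Degenerate segments
fall back to odd reflection.

**Double integration.** Discrete time-domain integration rules have a
frequency-dependent gain error of $(\omega T)^2/12$ per pass at phase step
$\omega T$; at 1000 Hz this is ~4 % per pass at 110 Hz and ~8 % per pass at
160 Hz — an 8–17 % displacement error across the analysis band, larger than
the effects being measured. The default integrator therefore divides the
spectrum by $(j\omega)^2$ (exact for in-band content), suppresses content
below half the band edge (37.5 Hz), and removes any residual best-fit line.
The literal cumulative-trapezoid variant, with linear detrending after each
pass, is available as `stiffness_params(integration = "trapezoid")` for
comparison.

**Degenerate windows.** Windows whose deformation depth falls below
`displacement_epsilon` (default 1 µm) are marked invalid with reason
`degenerate_displacement` and excluded from medians rather than clamped:
dividing by a near-zero displacement would manufacture arbitrarily large
stiffness values out of noise.

**Windowing.** Stiffness windows are non-overlapping, half-open, 1 s long,
with a trailing partial window dropped; ties in $|a|$ resolve to the
earliest sample.

## The EMG chain

Relaxed-muscle surface EMG is modelled as zero-mean Gaussian noise
band-limited to 20–450 Hz whose per-sample standard deviation is the
"envelope scale"; congestion-stage effects enter as multiplicative scale
factors per stage and leg. The feature chain is: full-wave rectification, a
zero-phase 2nd-order 10 Hz low-pass envelope (a documented software
stand-in for the electrode's onboard rectify-and-filter hardware, which
cannot be reproduced off the device), normalization of each leg's envelope
by the single peak across **all** of that leg's stages and conditions
(per-stage normalization would erase exactly the stage effects under
study), and windowed integrated EMG
$$ \mathrm{IEMG} = \sum_{i=1}^{N} |x_i| $$
over 256 ms windows sliding by 128 ms (at 1000 Hz: 256-sample windows, step
128). Whether the $x_i$ should be normalized-envelope samples or raw
rectified samples is ambiguous in the source design; we compute IEMG on the
normalized envelope, matching the stated processing order
(normalize, then extract features), and expose
`emg_params(on_normalized = FALSE)` for raw-envelope sensitivity analyses.

## Deltas and the comparison design

For each subject, leg and (for IEMG) vibration condition, the per-window
feature values of each stage are reduced to their median, and the baseline
median is subtracted: $\Delta(s) = \mathrm{med}(s) - \mathrm{med}(T0)$.
$\Delta(T0)$ is identically zero by construction. Stiffness deltas are
computed from vibration-on recordings only — without the stimulus there is
no oscillation to measure.

The statistical battery, per feature and vibration condition, is:

* each non-baseline stage vs `T0` within each leg, and
* experimental vs control leg at every stage,

all two-sided Mann–Whitney U tests on per-subject values (n = 8 per group),
with **no multiple-testing correction** — matching the original design; a
Holm option exists behind `correction = "holm"`. The sampling unit is the
per-subject median (not pooled windows), the natural reading of a design
with 8 animals; pooled-window analyses would pseudo-replicate.

**Exactness.** For the study's n = 8 + 8 scale the U test is exact: the
permutation distribution of the midrank sum over all
$\binom{16}{8} = 12870$ labelings is computed by dynamic programming over
integer doubled midranks, which enumerates tied data correctly;
$p = \min(1, 2\,P(U \le u_{\min}))$. Larger samples fall back to the normal
approximation with tie correction and continuity correction. A subtle and
deliberate consequence of the delta design: in stage-vs-baseline
comparisons the baseline group is eight exact zeros, so the test reduces to
a function of how many subject deltas are positive, and its exact attained
size is $18/256 \approx 0.070$ rather than 0.05. This is a property of the
published design, reproduced faithfully, and it is why the type-I
simulations below use an acceptance band up to 0.09. A second consequence
is that the leg-vs-leg comparison *at baseline* is deterministic — both
groups are eight exact zeros, so $p = 1$ always; the pipeline reports it
(matching the stage-at-a-time design) but no calibration statement can
apply to it.

**Normality screen.** The Kolmogorov–Smirnov statistic is computed against
a normal with estimated mean and sd; since parameter estimation invalidates
the classical KS null distribution, the p-value is calibrated by Monte
Carlo in the manner of the Lilliefors test (10,000 seeded replicates,
cached per sample size so repeated calls are cheap and reproducible). As in
the original design the screen gates nothing — the comparisons are
nonparametric regardless — and baseline delta cells (zero variance) are
reported as NA.

**Box plots.** Summaries use quartiles by linear interpolation, whiskers at
the most extreme points within $Q3 + 1.5\,\mathrm{IQR}$ /
$Q1 - 1.5\,\mathrm{IQR}$, and points beyond them as outliers.

## The synthetic experiment: what it does and does not emulate

`vc_scenario()` encodes the study conditions as defaults: 8 subjects, the
seven-stage protocol, 120 s vibration-on / 30 s vibration-off recordings at
1000 Hz, an experimental-leg stiffness ramp (1.0, 1.1, …, 1.6) emulating
progressive congestion-induced swelling, control-leg multipliers of 1.0,
and modest EMG amplitude factors whose direction (control leg up,
experimental leg down under vibration) follows the reported pattern.
Between-subject heterogeneity is lognormal on $k$, $M$ and EMG scale with a
10 % coefficient of variation — the source reports no between-animal
variance, and 10 % yields stage-significance patterns of the same shape as
the published figures. Sensor noise is white Gaussian (default 0.5 m/s²)
plus a low-frequency sinusoidal drift (0.2 m/s² at 0.8 Hz, random phase).
Seeding is hierarchical: a root seed plus a hashed label per
subject/leg/stage/condition/channel, so adding a stage or subject never
perturbs the other recordings and experiments are bit-reproducible.

The generator does **not** emulate: hemodynamics (venous velocities,
pressure gradients), nonstationary or heavy-tailed EMG, electrode motion
artifacts, vibration-transmission depth effects, multi-compartment tissue
mechanics, or any coupling between EMG and ACC channels. Passing tests
therefore demonstrate that the *feature extraction and statistical
machinery* behave as designed under the assumed signal model — not that the
biological effect sizes are as programmed.

## Simulation problem sizes

Replicate studies (type-I calibration, power patterns) use the full
8-subject design with shortened recordings — 2 s vibration-on, 1 s
vibration-off — because the Mann–Whitney tests operate on per-subject
medians, whose null distribution does not depend on the recording length;
1000 null replicates calibrate each comparison's rejection rate, and 200
effect replicates the power pattern. Single-recording accuracy checks use
5 s recordings so that mid-recording windows are far from both edges.

## Known limitations

* The stiffness estimator is physically meaningful only in impulse mode;
  in continuous mode it reports the drive frequency, a limitation inherent
  to the $m\,a_{\max}/\Delta l$ formulation rather than to this
  implementation.
* Estimator bias grows with tissue damping (see above); beyond
  $\zeta \approx 0.02$ the 1-second ring-down no longer survives band-pass
  filtering unscathed.
* The exact U test's attained size under the delta design is 0.07 for
  stage-vs-baseline comparisons (eight tied zeros in the baseline group);
  interpret per-comparison significance accordingly.
* The S1-style supplementary reader is configuration-driven because the
  deposited workbook's internal layout is not documented; XLSX input needs
  readxl, CSV input has no extra dependency.

## A minimal run

```{r, eval = FALSE}
sc <- vc_scenario(seed = 1)                 # full 8-pig protocol
run <- run_full_pipeline(run_config(scenario = sc, out_dir = "vc-out"))
run$comparisons[run$comparisons$feature == "delta_stiffness", ]
plot_deltas(run$delta_table)                # Fig-style stage box plots
```
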