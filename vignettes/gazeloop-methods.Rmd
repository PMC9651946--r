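---
title: "Methods: nested feedback decomposition for gaze stabilization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nested feedback decomposition for gaze stabilization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeloop)
```

## The control model

Gaze stabilization about the yaw axis is modeled as two coupled feedback
loops. A visual perturbation `R` (the angular position of a wide-field
grating) produces retinal slip, the sensory error

```
E = R − H − B,
```

where `H` is head angle (relative to the body) and `B` body angle. Two
sensorimotor transforms drive the head: a visual transform `G_v` from `E`
to `H`, and a mechanosensory transform `G_m` from `B` to `H` (haltere
encoding of body rotation). The body has analogous transforms `G_bv` (from
`E`) and `G_bm` (from `B`, a damping term). Each transform is the product
of a neural controller and the passive biomechanics of its plant, and each
carries a pure sensory delay — about 30 ms for vision, about 5 ms for the
halteres. The loop equations are

```
H = G_v E + G_m B,        B = G_bv E + G_bm B.
```

Because `B` is itself driven by the visually induced error, the
mechanosensory pathway is *nested* inside the visual loop. Solving for the
closed-loop head response splits it into three addends,

```
H/R = G_v/(1+G_v) − G_v/(1+G_v)·B/R + G_m/(1+G_v)·B/R,
```

head-visual, body-visual, and body-mechanosensory feedback. Every
decomposition operation in the package (`closed_loop_head_free()`,
`predict_visual_only()`, `predict_mechano_only()`, `estimate_Gm_self()`,
`estimate_Gm_external()`, `feedback_weighting()`) is element-wise complex
algebra on this structure, evaluated non-parametrically on a shared
frequency grid — no transfer-function model is ever fitted to data.

Assumptions inherited by everything downstream: approximately linear
time-invariant dynamics within a trial; visual feedback with gain −1
(motion in one direction produces equal and opposite optic flow); neck
proprioception not modeled (it is present identically in every
configuration the algebra compares); yaw only.

### Sign conventions

Two algebraically delicate points are exposed explicitly rather than
resolved silently:

* the mechanosensory addend enters the closed loop with a **plus** sign
  (the damping character of `G_m` lives in its phase, around −100°, not in
  the sign of the term). The package uses this convention throughout; the
  test suite asserts the equivalent one- and two-term forms agree under
  it.
* for motor-replay experiments (body motion imposed, display co-rotating,
  so `E = −H`), `estimate_Gm_external()` returns the estimate under two
  conventions: `as_printed` computes `(1 − G_v)·H/B`, `rederived` computes
  `(1 + G_v)·H/B`, which is what direct re-derivation from `E = −H` gives
  (and what recovers the simulator's ground truth exactly). Both columns
  are always present; `as_printed` fills the default `Gm` column. Ratios
  between two replay estimates under one convention are unaffected by the
  choice, which is why the pipeline's gating contrast compares replay runs
  at gate 1 versus gate 0.1 rather than mixing estimator families.

## The synthetic fly

`default_fly()` is the package's synthetic-data generator core: a
documented set of loop components whose closed-loop behavior reproduces
the qualitative structure of measured fly gaze stabilization, with all
numeric values module constants. Design targets, in order of priority:

* the **body** acts as a low-pass tracker: closed-loop `B/R` gain near 1
  at 0.7 Hz falling to well under 0.1 at 10.6 Hz, with moderate phase lag;
* the **body-free head** responds weakly at low frequency (the body has
  already cancelled most of the error), shows a low-frequency phase lead,
  and never reaches the ±15° neck limit for the standard 250 deg/s
  battery;
* the **body-fixed head** operates at distinctly higher gain and is driven
  to the neck limit only at the lowest battery frequency — so the
  saturation-corrected LSSA path is exercised where saturation genuinely
  occurs and nowhere else;
* `G_m` is high-pass (differentiating) with phase near −100°, so the
  mechanosensory head drive destructively interferes with the visual
  drive: folding it in *lowers* closed-loop head gain across the battery
  (active damping), which the decomposition tests assert as ordering
  relations.

`sim_config()` collects the tunable parameters: tracking-noise SD (deg;
default 0.25, white Gaussian on the *measured* angles — the noise source
in the emulated preparation is video tracking, not motor noise), neck
limit (deg; default 15), `mech_gate` in [0, 1] scaling the mechanosensory
drive to the head (1 for self-generated body motion, 0.1 as the default
for externally generated motion — a scalar stand-in for the nonlinear,
context-dependent gating; the biological mechanism is not modeled), output
rate 100 Hz (video rate), internal rate 1 kHz, and the discarded
transient (2 s).

What the generator deliberately does **not** emulate: display quantization
and LED-panel rendering, wing/aerodynamic dynamics, roll and pitch,
trial-to-trial nonstationarity, and any real across-animal variability in
the loop components (synthetic "flies" share one truth and differ only in
noise). Passing recovery tests therefore demonstrates correctness of the
identification and algebra under the model's assumptions — not that real
flies satisfy them.

## Numerical choices

* **Discretization.** Transforms are discretized by the bilinear transform
  at the 1 kHz internal rate; pure delays become integer internal samples
  (5 ms = 5 samples — representable only because the internal rate exceeds
  the 100 Hz output rate). Since every transform carries at least one
  sample of transport delay, the feedback loop is solvable sample by
  sample with no artificial computation delay; the discrete loop matches
  the continuous closed form to ~0.1% across the battery. The head clamp
  is applied to the head output each internal step (state clamping, no
  further anti-windup machinery); simulations start from rest and the
  initial transient is discarded.
* **Stimulus synthesis.** The internal-rate stimulus is synthesized
  analytically from the perturbation spec. (Upsampling the 100 Hz samples
  by linear interpolation would attenuate a 10.6 Hz component by ~4% —
  larger than the identification errors being measured.)
* **Chirp-z spectra.** Bluestein's FFT-based chirp-z algorithm evaluates
  the spectrum on the 0–50 Hz grid in 0.05 Hz steps; the normalization is
  sine-referenced (a unit sine at a grid frequency has magnitude 1 and
  phase equal to its sine phase). Trials are analyzed over windows that
  hold a whole number of cycles of every 0.05 Hz-grid component (20 s by
  default).
* **Preprocessing.** Least-squares linear detrend, then a zero-phase
  (forward–backward) 2nd-order Butterworth low-pass at 40 Hz. Zero-phase
  filtering is essential because phase is a primary output.
* **Division floors.** FRF ratios are flagged invalid (never divided)
  where the input magnitude falls below 1e-8; closed-loop formulas flag
  frequencies where `|1+G_v|` < 1e-8; `estimate_Gm_self()` flags
  frequencies where `|B/R|` < 1e-3 (one cannot infer a B-to-H transform
  where the body barely moves). Flagged frequencies are excluded, not
  regularized — the analysis only reports at stimulus frequencies where
  responses are strong.
* **Saturation correction.** Samples within 5% of the neck limit whose
  velocity is below a floor (default 15% of the peak velocity an
  at-the-limit sinusoid would reach) are masked; a three-parameter
  sinusoid is refit by linear least squares on the rest; the
  corrected/uncorrected amplitude ratio rescales FRF **gain only** —
  phase is untouched. Correction is refused when >90% of samples mask.
* **Across-animal statistics.** Gain and compensation error average
  arithmetically with sample SDs; phase uses the circular mean and
  circular SD (`sqrt(-2 log R̄)`). Averaging operates on gain/phase, not
  complex values (the complex mean is available as a diagnostic).
* **Uncertainty propagation.** Decomposition formulas combine transforms
  measured in different animal groups, so dispersions are propagated by
  seeded Monte Carlo: per-frequency normal draws on gain, wrapped-normal
  on phase, independent across groups, ≥100 draws.
* **τ fitting.** `θ(t) = θ₀ e^{−t/τ} + θ_∞` by Levenberg–Marquardt with a
  log-linear initialization, over a 1 s window after the saccade offset;
  fits with R² < 0.5 are unreliable and excluded.

## Problem sizes and the saccade generator

The standard pipeline run uses 5 synthetic flies, the seven-frequency
battery at 250 deg/s, 20 s analysis windows (2 s transient), and 0.25°
noise; motor-replay estimates average 6 replay animals per gate. The
saccade analysis uses 110 ten-second trials per condition. Saccade
amplitudes are drawn from N(8°, 2°) truncated to [6°, 15°] and durations
from N(70, 15) ms truncated to [40, 100] ms, so every injected event's
peak velocity (2·amplitude/duration ≥ 120 deg/s) clears the default
100 deg/s detection threshold, and the inter-saccade floor (1.1 s) exceeds
the 1 s fit window so nearly every event yields a τ. These choices give
roughly 400–550 τ-bearing events per condition, the scale of a real
multi-animal saccade data set, with return time constants of 0.1 s
(body-free) versus 0.8 s (body-fixed) — an 8× contrast.

## Known limitations

* With the 1 s window, τ estimates for the slow condition (τ = 0.8 s) are
  strongly right-skewed (the window holds barely one time constant), so
  mean-based tests on τ can be indecisive while the rank-sum test is
  decisive; the package reports both, and median ratios are the
  recommended effect size.
* The saturation correction assumes the unclipped portions of a clipped
  cycle still follow the underlying sinusoid; under heavy clipping in
  closed loop this is only approximate, which is why the default fly is
  tuned so saturation is mild and confined to the lowest frequency.
* Coherence uses trial-averaged spectra across animals (no segmenting or
  windowing within a trial); it needs at least two trials and is reported
  at stimulus frequencies only.
* `mech_gate` is a scalar; real gating is presumably dynamic and
  state-dependent.
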