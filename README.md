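# gazeloop

Flies stabilize gaze with compensatory head and body turns driven by
wide-field visual motion. Because the body's own rotations are sensed by the
halteres, mechanosensory feedback is **nested** inside the visual loop: it is
switched on by visually guided locomotion rather than by the stimulus itself.
Teasing such nested loops apart from behavior alone is hard — every measured
signal is shaped by all of them at once.

`gazeloop` is an R package for analysts of closed-loop sensorimotor behavior.
It implements, end to end and fully reproducibly:

* **velocity-normalized visual perturbations** — single sinusoids
  `R(t) = (v/2πf) sin(2πft)` and nine-component sums of sines, with every
  component's peak angular velocity fixed at `v`;
* **a closed-loop LTI simulator** of the gaze stabilization circuit
  (body-free, body-fixed, and motor-replay paradigms) with neck-joint
  saturation at ±15°, ~30 ms visual and ~5 ms haltere delays, and
  video-tracking noise — the synthetic-data generator that makes every
  downstream stage testable;
* **non-parametric system identification** — chirp-z spectra on a 0–50 Hz
  grid (0.05 Hz steps), frequency-response functions (gain, phase,
  coherence), compensation error `ε = |1 − X(s)|`, saturation-corrected
  least-squares spectral analysis for clipped head responses, circular
  statistics across animals, and Monte Carlo uncertainty propagation;
* **the feedback-decomposition algebra** at the package's core. With
  `G_v` the visual error-to-head transform and `G_m` the body-to-head
  mechanosensory transform, the closed-loop head response of a body-free
  animal splits into three addends:

  ```
  H/R = G_v/(1+G_v)  −  G_v/(1+G_v) · B/R  +  G_m/(1+G_v) · B/R
        head visual      body visual          body mechanosensory
  ```

  The package evaluates each term, predicts the visual-only and
  mechanosensory-only loops, inverts the algebra to estimate the hidden
  `G_m` from self-generated body motion, estimates it independently from
  motor-replay (externally generated) body motion, and forms the
  mechanosensory-vs-visual weighting ratio `G_{v+m}/G_v`;
* **saccade analysis** — velocity-threshold detection with hysteresis,
  kinematics, post-saccade exponential damping constants τ, and group
  comparisons (Wilcoxon rank-sum, t, F tests).

## A worked example

Simulate one noisy trial of the default synthetic fly at 2.1 Hz, identify
the closed-loop transforms, and compare with the analytic loop solution:

```r
library(gazeloop)

fly   <- default_fly()
stim  <- single_sine(2.1, v_norm = 250, duration = 12)   # peak velocity 250 deg/s
trial <- simulate_trial(fly, stim, sim_config(seed = 1)) # 0.25 deg tracking noise

pp <- preprocess(trial[, c("time_s", "stimulus_deg", "body_deg", "head_deg")])
head_fr <- frf(pp[, c("time_s", "stimulus_deg")], pp[, c("time_s", "head_deg")],
               stim_freqs = 2.1)
dplyr::filter(head_fr, is_stim)
#>   freq_hz response              gain phase_deg is_stim valid
#> 1     2.1 0.2309323-0.0906033i 0.248     -21.4 TRUE    TRUE

closed_loop_truth(fly, 2.1)$H_over_R
#> [1] 0.2311079-0.0895631i
```

The identified head transform (gain 0.248, phase −21.4°) matches the
analytic closed loop to a fraction of a percent. The compensation error at
this frequency is 0.774: the head alone cancels about a quarter of the
retinal slip, the rest is handled by the body (body gain 0.52 here) or left
uncompensated. `run_pipeline(run_config(), out_dir)` chains the whole
workflow — batteries of body-free/body-fixed trials for several synthetic
flies, identification with saturation correction, the three-term
decomposition, both `G_m` estimators, the weighting ratio, and the saccade
damping comparison — into one reproducible, manifest-hashed output
directory.

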