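# fourlink

Planar four-link dynamics of a cat hind leg for analysing memory-guided
stepping over a remembered barrier.

When a cat steps over a barrier with its forelegs and walks on after the
barrier has been lowered, the hind legs still step high enough to clear the
remembered obstacle, and the upslope of the toe trajectory depends on how
far the toe starts from the barrier.  `fourlink` implements the
computational machinery needed to ask how much of that dependence is
mechanical (leg geometry) and how much requires rescaled motor commands:

* a **four-link rigid-rod model** (thigh, shank, paw, toes; uniform rods,
  `I = m a²/3`) whose twenty Newton–Euler equations — per segment
  `f_x1 − f_x2 = m ẍ`, `f_y1 − f_y2 − m g = m ÿ`,
  `τ₁ − τ₂ + a sinθ (f_x1+f_x2) − a cosθ (f_y1+f_y2) = I θ̈`, plus two
  kinematic-chain equations — are solved as one 20×20 linear system per
  1-ms step, in inverse mode (torques from kinematics) or forward mode
  (accelerations from torques);
* a **motion-capture pipeline**: knee triangulation from hip and ankle
  markers, zero-phase 2nd-order Butterworth filtering (10 Hz) of segment
  angles, cubic-spline resampling to 1 ms, finite-difference velocities and
  accelerations, swing-onset detection, and the toe-trajectory slope
  (2 cm of rise / horizontal progress between 3 and 5 cm elevation);
* **forward simulation** by fixed-step 4th-order Runge–Kutta (1 ms,
  zero-order-held torques) and the **fixed-command experiment** that drives
  every initial geometry with the averaged long-distance (16–25 cm) torque
  profile;
* **EMG burst quantification** (full-wave rectification, zero-phase 50-Hz
  low-pass, 150-ms trapezoidal integral from burst onset);
* a **synthetic-trial generator** with exact ground truth (markers at
  60 Hz, EMG at 1 kHz, distance-modulated knee flexion pulses) so the whole
  pipeline is testable without animal recordings.

## Worked example

```r
library(fourlink)

leg  <- leg_model()                         # default cat parameters
spec <- cohort_spec(n_trials = 30, seed = 21)
coh  <- generate_cohort(leg, spec)          # 30 synthetic trials

fit <- fit_swing_dynamics(coh$trials[[1]], leg)
fit
#> Four-link swing-dynamics fit of trial 'synth_001'
#>   toe-to-barrier distance: 21.7 cm
#>   toe-trajectory slope (3-5 cm): 3.482
#>   initial torques (30 ms): hip +0.261, knee -0.098, ankle +0.016 N m
#>   EMG burst magnitude [ST, Sart_m, IP]: 0.031, 0.020, 0.115 AU s
```

The fit is a classed model object: `coef(fit)` returns the 30-ms initial
joint torques, `simulate(fit)` re-drives the forward model with the
estimated torque profile, and `residuals(fit)` gives the observed-minus-
resimulated toe path (sub-millimetre on noiseless trials — the check that
the numerical integration reproduces the measured movement).

The full analysis reproduces the study's comparison per animal:

```r
an <- run_full_analysis(coh$trials, leg)
an
#> Barrier-stepping analysis: 30 trial(s) analysed, 0 excluded, 1 animal(s)
#> animal A:
#>   actual_slope_vs_distance         slope -51.385, R^2 = 0.822, p = 5.4e-12, n = 30
#>   simulated_slope_vs_distance      slope -8.927, R^2 = 0.948, p = 1.5e-19, n = 30
#>   simulated_vs_actual_slope        slope +0.150, R^2 = 0.863, p = 1.4e-13, n = 30
#>   hip_tau0_vs_distance             slope -0.030, R^2 = 0.019, p = 0.47, n = 30
#>   knee_tau0_vs_distance            slope +0.143, R^2 = 0.606, p = 4.1e-07, n = 30
#>   ankle_tau0_vs_distance           slope -0.001, R^2 = 0.002, p = 0.81, n = 30
#>   emg_ST_vs_distance               slope -0.125, R^2 = 0.945, p = 3.4e-19, n = 30
#>   ...
```

Read: both observed and fixed-command simulated slopes rise as the start
nears the barrier (negative distance regressions) — the mechanical
contribution — but the simulated-vs-actual slope is well below 1, so a
fixed command cannot explain the full steepening; consistently, the initial
knee flexion torque and the knee-flexor (ST) EMG burst grow with proximity
while hip and ankle torques stay flat.  `plot(an)` draws the slope-distance
scatter and the model-vs-data identity plot; `plot(fit)` draws stick
figures and torque profiles for one trial.

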