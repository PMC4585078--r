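---
title: "Methods: four-link dynamics of memory-guided hind-leg stepping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: four-link dynamics of memory-guided hind-leg stepping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fourlink)
```

## The scientific question

When a cat steps over a barrier with its forelegs, stops, and later resumes
walking after the barrier has been removed, its hind legs still step high
enough to clear the remembered obstacle.  The upslope of the toe trajectory
early in swing depends strongly on how far the toe starts from the
(remembered) barrier: nearer starts produce steeper trajectories.  The
question this package's analysis addresses is how much of that dependence is
*mechanical* — a consequence of the leg's initial geometry — and how much
requires *neuronal* rescaling of the motor command.  The strategy is: (1)
estimate swing-phase joint torques per trial by inverse dynamics; (2) drive a
forward simulation of the same leg with one fixed torque command (the average
of trials starting far from the barrier) from every trial's initial geometry;
(3) compare the simulated slope–distance relation with the observed one, and
corroborate with the distance dependence of the initial knee flexion torque
and of knee-flexor EMG burst size.

## The mechanical model

The hind leg is modelled as four uniform rigid rods — thigh, shank, paw,
toes — pinned at the hip, knee, ankle and paw joints, moving in the sagittal
plane about a fixed hip.  Default parameters (masses 200/100/40/20 g,
lengths 10/11/5/2 cm) are typical adult-cat values; for a uniform rod of
mass $m$ and half-length $a$, $I = \tfrac13 m a^2$ about the centre of mass.
Segment angles $\theta_i$ are measured anticlockwise from the positive
$x$-axis; positive torques are anticlockwise, so for this leg orientation
(rightward walking, right hind leg) knee *flexion* torque is negative while
hip and ankle flexion torques are positive.

Each segment contributes three Newton–Euler equations,
$$f_{x1}-f_{x2}=m\ddot x,\qquad f_{y1}-f_{y2}-mg=m\ddot y,$$
$$\tau_1-\tau_2+a\sin\theta\,(f_{x1}+f_{x2})-a\cos\theta\,(f_{y1}+f_{y2})=I\ddot\theta,$$
and two kinematic-chain equations expressing its centre-of-mass acceleration
through the angles, angular velocities and angular accelerations of itself
and all more proximal segments.  That yields twenty linear equations in
twenty unknowns per time step.  In *inverse* mode the unknowns are the four
joint torques, eight joint interaction forces and eight centre-of-mass
accelerations; in *forward* mode the torques are known and the four angular
accelerations take their place.  Both modes are two labelings of one
assembly routine and one linear solve (`solve()` on the dense 20×20 system),
which makes their duality directly testable: torques obtained from inverse
mode, fed back through forward mode, reproduce the input accelerations to
$10^{-9}$ relative error.  Two closed-form oracles anchor the solver: a
motionless posture must give each joint the gravitational moment of all
distal mass (for the fully horizontal leg the hip carries
$g\sum_i m_i x_{\mathrm{com},i} = 0.3953$ N m), and when the distal masses
are scaled to $10^{-9}$ of their defaults the thigh behaves as a uniform-rod
pendulum with small-oscillation period $2\pi\sqrt{2L/3g} = 0.518$ s.

The hip is a fixed inertial origin — the chain equations contain no
base-translation terms — so trunk translation is ignored.  No muscle
models, moment arms, viscoelasticity, joint limits or ground contact are
included; torque is treated as a proxy for the neural command.

## Motion-capture processing

Trials arrive as 60-Hz, 2-D marker series (iliac crest, hip, ankle, paw
joint, toe tip; centimetres on disk, SI internally).  The knee cannot be
tracked directly (skin movement), so it is reconstructed per frame as the
circle–circle intersection at thigh length from the hip and shank length
from the ankle, taking the anterior solution; hip–ankle distances outside
the reachable annulus raise an error unless within tolerance, in which case
the collinear boundary is used.  Segment angles are `atan2` of each
proximal→distal vector, unwrapped in time, low-pass filtered with a
zero-phase 2nd-order Butterworth at 10 Hz, and cubic-splined to a 1-ms grid.
Zero-phase (forward–backward) filtering is used because the analysis is
offline and phase lag would bias onset and slope timing; the effective
attenuation at the cutoff is therefore −6 dB.  The filter is applied with
odd-reflection end padding so constants pass exactly (the plain
forward–backward filter otherwise leaks end transients).

Derivatives are 1-ms finite differences applied twice.  One numerical
subtlety matters: the raw forward difference $(x_{k+1}-x_k)/\Delta t$
estimates the derivative at $t_k+\Delta t/2$, not $t_k$.  Using it
unshifted gives torque series that lead the kinematics by about half a
sample, which biases the inverse→forward verification round trip by
roughly 1.5 mm of toe position over 200 ms.  The pipeline therefore
re-centres the differences (mean of the two adjacent forward differences,
i.e. a central difference, one-sided at the ends), which brings the round
trip to ~0.4 mm; the plain forward form remains available as
`differentiate()`.

The toe tip is digitized in its own right, so trial metrics (swing onset,
trajectory slope, initial toe-to-barrier distance) are measured on the
spline-resampled toe-marker path rather than on the forward kinematics of
the filtered angles; the angle-based path is the reference for the
model-verification residuals, where simulated and observed kinematics must
be compared on the same footing.

Swing onset is the first sample at which toe height exceeds its standing
baseline (median of the first 100 ms) by 0.5 cm and stays there for at
least 50 ms — an operational rule, configurable, chosen because the source
analyses measure "soon after swing commences" without defining onset.  The
trajectory slope is $0.02/\Delta x$ m/m as the toe first rises through 3 cm
and then 5 cm above ground (crossings by linear interpolation).  Initial
joint torques are the mean over the first 30 ms from onset (the highlighted
early-swing window; whether the original statistic was a window mean, onset
value or peak is not stated — the window mean is used and the window is an
argument).

## Forward simulation and the fixed-command experiment

Forward dynamics integrates the same twenty equations with a fixed-step
fourth-order Runge–Kutta scheme at 1 ms, torques zero-order-held between
samples.  Torque-free simulations conserve mechanical energy to better than
0.1% over 0.5 s, and halving the step moves the 200-ms toe position by less
than $10^{-6}$ m.

The central experiment drives the model with the *average* torque profile of
the long-distance subset (initial toe-to-barrier distance 16–25 cm,
inclusive; the short-distance comparison subset is < 8 cm) and the average
initial angular velocities of the same subset, from each trial's own initial
angles.  Any slope–distance dependence that survives is purely mechanical.
The per-animal analysis then regresses: actual slope on distance, simulated
slope on distance, simulated slope on actual slope (OLS slope < 1 means the
fixed command under-predicts the steepening seen in the data, implying a
neuronal contribution), initial hip/knee/ankle torque on distance, and EMG
burst magnitude on distance.  Regressions are ordinary least squares with a
two-sided $t$-test on the slope ($n-2$ df), raw p-values, no
multiple-testing correction, animals never pooled.

## EMG quantification

Each channel (semitendinosus ST and medial sartorius Sart\_m, knee flexors;
iliopsoas IP, hip flexor) is full-wave rectified and low-pass filtered
(zero-phase 2nd-order Butterworth, 50 Hz); burst magnitude is the
trapezoidal integral of that envelope over 150 ms from burst onset.  Burst
onset — not defined in the source analyses — is detected where the envelope
exceeds the baseline mean + 3 SD (baseline = first 100 ms) for at least
20 ms, then backtracked to the last sample at or below baseline + 1 SD so
that the window starts at the beginning of the rise rather than at the
amplitude-dependent threshold crossing; all constants are arguments.  Even
so, onset localisation on a low-pass-smoothed stochastic rise runs a few
milliseconds late on weak bursts, which inflates burst magnitudes (and the
recovered magnitude–distance trend) by roughly 5%; this is a property of
envelope-threshold EMG timing generally, not of the synthetic data.

## The synthetic-trial generator

No animal recordings are distributed, so the package generates complete
synthetic trials with known ground truth; every pipeline stage is tested
against that truth.  The generator is not a neutral noise source — its
defaults *are* the study conditions the analysis assumes:

* **Posture family.**  Standing postures are a one-parameter family anchored
  at 25 cm (extended: thigh −70°, paw −65°, toe −5°) and 5 cm (flexed:
  thigh −60°, paw −72.5°, toe −10°) from the barrier, with the shank angle
  solved from the toe-on-ground constraint at a fixed 0.23-m hip height.
  Nearer starts have a monotonically more flexed knee and ankle — the
  geometric regularity seen in stepping animals — and the anchor angles
  were chosen (by pilot simulation) so that the resulting dynamics sit in
  the regime where the trajectory-slope metric responds monotonically to
  both geometry and knee-torque changes; outside that regime (nearly
  vertical toe paths) the 3–5 cm slope degenerates.
* **Commands.**  During a 300-ms standing prefix each trial is held
  stationary by its own posture's static torques.  At command onset the
  torques step to a swing command common to all trials — the static hold of
  the reference (most extended) posture plus raised-cosine-edged flexion
  pulses (hip +0.22, knee −0.025, ankle +0.005, paw +0.0005 N m; rise
  50 ms, duration 190 ms) — except that the knee pulse amplitude grows
  linearly with proximity (−0.15 N m per metre, so −0.025 N m at 25 cm to
  −0.055 N m at 5 cm).  With the modulation gain set to zero every trial
  receives an identical swing command, which realises the "purely
  mechanical" control condition exactly: the model-vs-actual slope
  regression must then sit at 1, and does (checked across seeds).  Pulse
  amplitudes were calibrated once so swings are stable (no flailing of the
  light distal segments), clear the 6.5-cm barrier height comfortably, and
  reproduce the qualitative slope range of observed stepping; the timing
  puts the 30-ms initial-torque window on the pulse plateau for all
  detection lags, so hip and ankle initial torques are exactly
  distance-flat, as reported for the animals.
* **Measurement.**  Markers are sampled at 60 Hz with i.i.d. Gaussian noise
  (0.5 mm SD, typical optical-capture error).  EMG (1 kHz, a stated
  assumption — the original rate is unreported) is a white-Gaussian carrier
  amplitude-modulated by the driving joint's pulse (8, 6 and 5 AU per N m
  for ST, Sart\_m, IP) over a 0.05-AU noise floor; its expected rectified
  envelope is computable in closed form, giving a ground-truth burst
  magnitude.
* **Reproducibility.**  All randomness flows from the single cohort seed;
  identical specs give bit-identical cohorts.

What the generator does *not* emulate: trunk/hip translation during swing,
ground contact (the unconstrained toe sweeps back ~1 cm before lifting,
so the distance measured at detected onset sits slightly behind the nominal
standing distance), muscle dynamics, skin-marker artifacts beyond white
noise, inter-animal variability (pseudo-animal labels are available but the
default cohort is one animal), and any distribution of starting distances
other than uniform.  Passing tests therefore demonstrate that the
*pipeline* recovers the structure the model generates under realistic
capture noise — not that real cats obey the generator.

## Test conditions and numerical choices

Problem sizes in the test-suite and acceptance script were chosen to make
each property sharp at desk scale: 1000 random states for the duality
bound; 20 noiseless trials for the verification round trip (toe path within
1 mm over 200 ms, slope within 5%); a 50-trial default cohort for the
fixed-command monotonicity (Spearman ρ < −0.9); 12-trial noiseless cohorts
for the model-vs-actual slope contrast (the no-modulation control is run
without marker noise because regression dilution — noise in the
actual-slope regressor, amplified for steep trajectories — otherwise biases
the OLS slope below 1 for reasons unrelated to the mechanics); a 24-trial
noiseless cohort for gain recovery within 10%; and two independent 50-trial
default-noise cohorts (pooled to n = 100 for the 25% recovery bound) for
the significance structure.  The flat-joint checks use a replication rule —
knee-torque and knee-flexor EMG trends must be significant in both
cohorts, while no hip/ankle torque or IP trend may be significant in both —
because each flat regression is a true null, so a lone p > 0.05 assertion
on a single cohort would fail a twentieth of the time by construction.

Other numerical choices: knee-triangulation tolerance 1 µm at the operation
level but 2 mm in the pipeline (marker noise near full extension);
simulation divergence is declared at |angular velocity| > 10³ rad/s;
degenerate regressions (constant predictor) error out and are reported as
not estimable; a constant response returns $R^2 = 0$, $p = 1$.

## Known limitations

The fixed-hip assumption ignores pelvic translation, which in walking
animals adds to toe progression; absolute slopes here are therefore steeper
than treadmill-derived values.  The model-vs-actual comparison inherits a
small compression (~4–8%) from residual attenuation of the recovered
average command through the 10-Hz filter chain; it is visible in the
no-modulation control's confidence interval and should be kept in mind when
interpreting slopes just below 1.  The EMG model is deliberately minimal —
sufficient for burst-magnitude metrics, silent on spectra and units.
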