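---
title: "Methods: perturbation design, biomechanical model and response analysis"
author: "tiltpost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perturbation design, biomechanical model and response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiltpost)
```

## The problem

Standing balance is probed experimentally by tilting the support surface a
standing subject is on and measuring the corrective response. During a
rotational tilt, the platform's angular acceleration and its peak angular
velocity are normally confounded: a faster tilt is also a harder-accelerating
tilt. `tiltpost` implements an analysis pipeline for experiments that break
this confound — trapezoidal velocity profiles in which peak acceleration and
peak velocity are set independently while the total rotation is held fixed —
and quantifies the resulting postural response in two temporal phases: a
short-latency window (0–100 ms after perturbation onset) and a medium-latency
window (100–200 ms). The scientific structure the pipeline is built to detect
is a dissociation: short-latency responses scale with stimulus acceleration,
medium-latency responses with peak velocity.

The measured signals are head kinematics from a head-mounted IMU (angular
velocity per axis in deg/s, linear acceleration in m/s²) and the four
vertical footplate forces of a quadrupedal force plate, recorded at
1,000 samples/s. Because the underlying animal dataset is not publicly
deposited, the package ships a first-class synthetic-trial generator that
emulates the study's data structure with injectable ground truth; every
pipeline stage is exercised against that generator.

## Perturbation design

A condition is defined by axis (pitch or roll), direction (forward/backward,
leftward/rightward), peak acceleration $A$ (deg/s²), peak velocity $V$
(deg/s) and total displacement $D$ (deg). The command is built from a
piecewise-constant acceleration profile: $+A$ for $d_1 = V/A$, zero for
$d_2 = (D - V^2/A)/V$, then $-A$ for $d_1$. The profile is feasible only when
$V^2/A \le D$; at equality the plateau vanishes and the velocity profile is
triangular. Velocity and position follow by exact analytic integration, so
the final position equals $D$ to machine precision regardless of the command
grid.

```{r design}
base <- perturbation_spec("pitch", "forward", peak_accel = 500, peak_vel = 40)
unlist(phase_durations(base))
w <- design_waveform(base)
tail(w$pos_deg, 1)
```

Two design choices deserve note:

* **Continuous-time construction.** The physical platform updates at
  100 samples/s, and some block durations are not grid multiples (e.g.
  $V = 60$, $A = 500$ gives $d_2 = 0.0467$ s). We construct the profile in
  continuous time and sample the analytic position on the grid, which
  preserves the displacement exactly; a grid-quantized variant
  (`design_waveform(..., quantized = TRUE)`) is available for studying the
  fidelity cost of a grid-locked controller.
* **Sign convention.** Forward pitch and leftward roll are positive,
  centralized in `direction_sign()`; every downstream inversion (mirrored
  pooling, direction-asymmetry gains) routes through it.

The study grid crosses five unique $(A, V)$ profiles — velocity set
$\{20, 40, 60\}$ deg/s at 500 deg/s², acceleration set $\{200, 500, 1000\}$
deg/s² at 40 deg/s, sharing the base profile — with four directions, giving
20 conditions, all with $D = 10$°.

## The conceptual dual-pendulum model

To give mechanical intuition for how passive properties alone shape the
response, the package implements a linear two-segment model: a trunk–limb
segment pivoting at the ankles, coupled to the rotating platform through
stiffness $k_{platform}$ and damping $c_{platform}$, and a head segment on a
neck with stiffness $k_{neck}$ and damping $c_{neck}$. With trunk and head
angles $\theta_1, \theta_2$ (rad, from vertical) and platform angle $\varphi$:

$$\tau_1 = -m_1 g l_1 \theta_1 - k_{platform}(\theta_1 - \varphi)
          - c_{platform}(\dot\theta_1 - \dot\varphi)$$
$$\tau_2 = -k_{neck}(\theta_2 - \theta_1) - c_{neck}(\dot\theta_2 - \dot\theta_1)$$

with $\ddot\theta_i = \tau_i / I_i$, integrated by an adaptive Dormand–Prince
4/5 scheme (`deSolve`, rtol $10^{-8}$, atol $10^{-10}$) with dense output at
the 1,000 samples/s analysis rate.

Numerical and modelling choices:

* **The gravity term is implemented as written above**, i.e. restoring (a
  hanging-pendulum sign). For an inverted pendulum the small-angle gravity
  torque would be destabilizing ($+m_1 g l_1 \theta_1$); the model's printed
  form is the restoring sign and we do not silently "correct" it. A
  `gravity_sign` switch supports sensitivity analyses under the inverted
  sign, where the closed-form equilibrium
  $\theta_1^\ast = k_{platform}\varphi_0 /(k_{platform} - s\, m_1 g l_1)$
  (sign $s$) remains valid whenever the denominator is positive.
* **The head segment carries no gravity or inertial-coupling term** — a
  deliberate simplification of the conceptual model, kept as such.
* Default parameters are representative rhesus segment values (trunk
  ≈ 4.5 kg, COM ≈ 0.18 m, trunk inertia ≈ 0.2 kg·m², head inertia
  ≈ 0.01 kg·m²); they are illustrative, not fits. Two named profiles bracket
  the qualitative regimes: `"platform-following"` (stiff platform coupling,
  compliant neck) and `"stabilizing"` (weak platform coupling, stiff damped
  neck). The stabilizing profile also provides the roll-axis base trace of
  the synthetic generator.

The model is validated against closed-form oracles rather than data: the
static equilibrium satisfies $\tau_1 = \tau_2 = 0$ exactly; damped step
drives converge to it below $10^{-6}$ rad; the undamped trunk oscillator
conserves $\tfrac12 I_1\omega_1^2 + \tfrac12(m_1 g l_1 + k_{platform})\theta_1^2$
to $10^{-6}$ relative; responses are linear in the drive; and stiffening the
neck over five decades monotonically locks the head to the trunk.

## Centre of pressure and stance criteria

CoP is computed from the four load cells as
$\mathrm{CoP_{Lat}} = ((F_{FL}+F_{HL}) - (F_{FR}+F_{HR}))/m$ and
$\mathrm{CoP_{AP}} = ((F_{FL}+F_{FR}) - (F_{HL}+F_{HR}))/m$. Two points:

* The fore-aft equation is parenthesized as (front sum) − (hind sum),
  mirroring the structure of the lateral equation.
* Units are **N/kg** — a mass-normalized force difference. Converting to a
  metric CoP position would require the footplate geometry, which is not
  part of the model; all downstream metrics and labels keep N/kg.
* Forces are used unfiltered by default; a zero-phase 2nd-order Butterworth
  low-pass is available (`lowpass_hz`) since whether the original pipeline
  filtered before the CoP computation is unstated.

Trial starts are gated by stance symmetry: < 10 N difference between front
and hind halves and between left and right halves, and head deviation < 10°
in every axis — all strict inequalities, so a deviation of exactly 10°
fails.

## Quality control

A trial is excluded if (i) its step-response flag is set (step detection is
video-based and upstream of this package; the flag is consumed as a
boolean), (ii) head velocity exceeds 20 deg/s anywhere in the 500 ms before
onset, or (iii) head velocity exceeds 400 deg/s anywhere from 500 ms before
onset to 500 ms after motion offset. "Head velocity" is applied per IMU axis
on absolute value by default (the channels are per-axis); a vector-norm mode
is available. Both limits are strict "exceeds" comparisons. Trials with
insufficient pre-onset data raise an error rather than silently passing.

## Response metrics

* **Windows** are half-open, $[0, 100)$ and $[100, 200)$ ms, so the 100 ms
  boundary sample is counted once.
* **Onset latency** thresholds the deviation from the baseline mean at the
  RMS of the mean-subtracted 500 ms pre-onset baseline ("RMS error" implies
  mean removal). A floor of $10^{-9}$ channel units keeps the noiseless
  baseline well defined, and an optional `consecutive` parameter (default 1)
  requires a run of suprathreshold samples, suppressing single-sample blips.
  Not-detected is a value (`NA`), not an error. Note that on single noisy
  trials the threshold equals the noise SD, so single-trial latencies are
  noisy; latencies are most meaningful on condition averages
  (`average_condition()`), which is how they are used in practice.
* **Displacements**: total angular displacement is the trapezoidal integral
  of angular velocity, total linear displacement the double trapezoidal
  integral of linear acceleration, both over the platform-motion span
  $[0, T]$ with $T$ the waveform's analytic end time. "Cumulative sum of the
  CoP response" is implemented as the trajectory path length
  $\sum_t |\Delta \mathrm{CoP}_t|$, consistent with the sway-literature
  meaning of trajectory length; the literal signed cumulative sum is an
  option (`cop_mode = "signed"`).
* **Pooling mirrored directions** (`invert_and_pool()`) negates the
  direction-odd head channels and mirrors the footplate forces (left/right
  swap for roll, front/hind swap for pitch), which flips the corresponding
  CoP channel through the CoP equations themselves.

## Asymmetry index

For two opposite directions of one profile, the within-direction
distribution collects the pairwise mean absolute percentage error (MAPE)
over all same-direction response pairs from both directions; for the
across-direction distribution one direction is inverted and the MAPE taken
over all pairs of the pooled set regardless of direction. The index is
mean(across) − mean(within); zero indicates mirror symmetry. Choices:

* **MAPE normalization is trace-level**:
  $100 \cdot \overline{|a - b|} / \overline{|r|}$. Per-sample percentage
  errors blow up at zero crossings of oscillatory responses; the trace-level
  form keeps percentage semantics while staying defined. `pairwise_mape()`
  defaults to reference normalization ($r = a$); `asymmetry_index()` defaults
  to the symmetric variant ($\overline{|r|}$ = mean of the two magnitudes)
  because unordered pair enumeration has no natural reference, making the
  index invariant to direction relabeling.
* **"All possible pairs regardless of direction" is read literally**: the
  across distribution includes same-direction pairs of the pooled set. A
  `cross-only` mode restricts to cross-direction pairs.
* **Inference** is a two-tailed Welch t-test between the two MAPE
  distributions (the t-test variant is otherwise unspecified; Welch avoids
  the equal-variance assumption), with p-values combined across animals and
  stimulus profiles per axis by Fisher's method,
  $X = -2\sum \ln p_i \sim \chi^2_{2k}$.
* **Known limitation**: pair MAPEs are not independent samples — every trial
  participates in many pairs, and the within pairs are a subset of the
  pooled across pairs — so the t-test is strongly conservative under
  symmetry (its empirical rejection rate in the package's calibration suite
  falls far below the nominal 0.05). The index itself is unbiased near zero
  under symmetry; the p-value should be read as conservative. A permutation
  null would calibrate it but is out of scope here.
* Pairs are computed on per-trial traces restricted to the platform-motion
  span; traces that are identically zero raise a degenerate-normalization
  error rather than returning infinity.

## Condition-dependence statistics

Animal and condition effects are tested with an unbalanced two-way ANOVA —
`value ~ animal + condition`, no interaction, Type-II sums of squares
(the standard main-effects choice when no interaction is modelled; it
reduces exactly to the classical balanced ANOVA on balanced tables) — at a
threshold of 0.025 per factor. When the condition effect is significant,
ordinary least squares of the pooled per-trial metric on the numeric
stimulus parameter quantifies the trend (slope in metric units per deg/s or
per deg/s²; two-sided slope test at 0.05). The gating is enforced by
`condition_trend()`; both computations remain directly callable. Degenerate
zero-residual tables (noise-free synthetic input) are resolved by the exact
limits: zero factor SS → p = 1, positive factor SS over zero residual →
p = 0.

## The synthetic-trial generator

`generate_trial_set()` emulates per-condition trial sets at the study's
scale: 20 conditions × 3 animals × 20 trials at 1,000 samples/s, spanning
500 ms pre-onset to 500 ms post-offset. Its defaults are the package's
statement of the emulated study conditions and are not adjusted per analysis:

| parameter | default | units | rationale |
|---|---|---|---|
| `short_accel_gain` | 2×10⁻³ | (N/kg)/(deg/s²) | ≈1 N/kg short-window CoP at the 500 deg/s² base |
| `medium_vel_gain` | 2.5×10⁻² | (N/kg)/(deg/s) | ≈1 N/kg medium-window CoP at 40 deg/s |
| `channel_gain` | 4 / 0.12 / 1 | per channel | head-velocity (deg/s) and head-acceleration (m/s²) unit scales relative to CoP |
| `onset_s` | 0.025 / 0.030 / 0.045 | s | response onsets within the ~20–60 ms range expected for head and CoP channels |
| `noise_sd` | 2 / 0.06 / 0.3 | deg/s, m/s², N/kg | trial-to-trial variability giving clearly detectable but noisy responses |
| `animals` | gains 1.00, 0.85, 1.15 | — | three subjects, ±15% scalar offsets, mean exactly 1 |
| `contamination_rate` | 0.1 | — | ≈10% of recorded trials fail QC |
| `direction_asymmetry` | 1 | — | mirror-symmetric by default; asymmetry is injectable |

The response added to each axis-relevant channel is built from two
boxcar-like basis functions occupying the short and medium windows, with
raised-cosine edges (20 ms) so onset-latency analyses are not degenerate.
The two plateau levels are solved from a 2×2 linear system so that the
noiseless grid window means equal the injected targets *exactly* — the
generator's ground truth is therefore well defined without calibration
constants. Pitch trials superpose this on a platform-following base (head
velocity = platform command); roll trials on the stabilized base simulated
from the dual-pendulum `"stabilizing"` profile. Forces are synthesized by
inverting the CoP equations with the required force differences split
equally across the two plates of each half (any valid split works; the
equal split is canonical and testable), on a baseline of a quarter body
weight per plate. Contaminated trials receive either a 25–35 deg/s baseline
offset or a 420–480 deg/s spike in the post-offset tail, and the
contaminated identity is recorded as ground truth.

Reproducibility: one master seed; each trial draws from a substream derived
from a per-trial counter, so identical specs regenerate byte-identical sets.

What the generator does *not* emulate — and therefore what passing tests do
not establish about real data: structured (non-white) physiological noise
and drift, trial-to-trial latency jitter, animal-specific response *shapes*
(offsets are scalar), nonlinear or saturating responses at the highest
accelerations, step responses (consumed only as an upstream flag), and any
coupling between head motion and the CoP beyond the injected common
structure.

## Problem sizes and runtime choices

The validation suite runs the full study-scale recovery (1,200 generated
trials) once, uses 500 seeded replicates for the symmetric-null calibration
of the asymmetry index and for the regression-null uniformity check, 400
replicates for the ANOVA type-I check, 1,000 seeded traces for the
onset-latency oracle equivalence, and exhaustive pair enumeration up to 6
trials per side for the asymmetry oracle. These sizes were chosen to give
stable Monte-Carlo estimates at desk scale.

## Known limitations

* The pendulum model is linear and small-angle; no contact, stepping, or
  head-on-trunk gravitational load. It is a conceptual regime illustrator,
  not a subject-specific biomechanical model.
* CoP is a normalized force signal (N/kg), not a metric position.
* The asymmetry t-test is conservative under dependence (above).
* Statistical results on synthetic data inherit the generator's simplified
  noise model; effect sizes recovered there say nothing about effect sizes
  in real animals, only that the pipeline recovers what was injected.
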