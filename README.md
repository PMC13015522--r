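# tiltpost

Analysis of rotational support-surface perturbations for primate postural
control: perturbation design that dissociates angular acceleration from peak
velocity, a conceptual dual-pendulum model of platform tilt responses, and
the response-quantification and statistics pipeline that goes with them.

## Who this is for

Labs studying standing balance with tilting platforms (hexapod/Stewart
platforms), where the support surface rotates in pitch or roll and the
response is read out from head kinematics (IMU) and centre-of-pressure (CoP)
from footplate load cells. The central experimental problem is that a
rotation's angular acceleration and its peak velocity are normally
confounded; this package designs stimuli that separate them and tests which
of the two governs each temporal phase of the response.

## What it computes

**Stimulus design.** Trapezoidal angular-velocity commands: constant
acceleration $+A$ for $d_1 = V/A$, plateau at $V$ for
$d_2 = (D - V^2/A)/V$, then $-A$ for $d_1$, integrating to exactly $D$
degrees (feasible iff $V^2/A \le D$). The study grid is 5 unique $(A,V)$
profiles × 4 directions = 20 conditions, all with $D = 10°$.

**Biomechanics.** A linear dual-pendulum model — trunk on the ankles coupled
to the platform, head on the neck — with torques
$\tau_1 = -m_1 g l_1\theta_1 - k_{platform}(\theta_1-\varphi) - c_{platform}(\dot\theta_1-\dot\varphi)$
and $\tau_2 = -k_{neck}(\theta_2-\theta_1) - c_{neck}(\dot\theta_2-\dot\theta_1)$,
$\ddot\theta_i = \tau_i/I_i$, integrated with an adaptive Runge–Kutta 4/5
scheme. It reproduces the two qualitative regimes: platform-following vs
head-in-space stabilization.

**Response metrics.** CoP from four load cells
($\mathrm{CoP_{Lat}} = ((F_{FL}+F_{HL})-(F_{FR}+F_{HR}))/m$, N/kg), window
means over the short-latency (0–100 ms) and medium-latency (100–200 ms)
windows, onset latency by a baseline-RMS threshold, displacement integrals,
and CoP path length. Trial QC excludes step responses, baselines above
20 deg/s, and head velocities above 400 deg/s.

**Statistics.** Unbalanced two-way ANOVA (animal × condition, Type II,
p < 0.025) gating a pooled regression on the stimulus parameter; a pairwise
MAPE asymmetry index between mirrored directions with Welch t-test and
Fisher combination.

**Synthetic data.** A seeded generator emulating the study's data structure
with injectable ground truth (gains, onsets, noise, per-animal offsets,
direction asymmetry, QC contamination), so the full pipeline is testable
end-to-end. See the methods vignette (`vignettes/tiltpost-methods.Rmd`) for
every modelling choice and its rationale.

## Worked example

```r
library(tiltpost)

base <- perturbation_spec("pitch", "forward", peak_accel = 500, peak_vel = 40)
unlist(phase_durations(base))
#>    d1    d2 total
#>  0.08  0.17  0.33
tail(design_waveform(base)$pos_deg, 1)
#> [1] 10
length(enumerate_conditions())
#> [1] 20
```

The base perturbation accelerates for 80 ms, rides its 40 deg/s plateau for
170 ms, decelerates for 80 ms, and rotates the platform exactly 10°.

A small end-to-end synthetic run (velocity set, pitch axis, 10 trials per
condition and animal):

```r
gen <- generator_spec(
  conditions = enumerate_conditions(default_protocol(accel_set = numeric(0)),
                                    directions = c("forward", "backward")),
  n_trials = 10, seed = 7)
man <- run_pipeline(run_config(generator = gen, seed = 7))
man$counts
#> conditions trials_generated      trials_kept      metric_rows
#>          6              180              163              489

man$trends[man$trends$set == "velocity" & man$trends$channel == "cop",
           c("window", "anova_p_condition", "regression_slope",
             "regression_se", "regression_p")]
#>   window anova_p_condition regression_slope regression_se regression_p
#> 5  short          8.11e-01               NA            NA           NA
#> 6 medium         4.92e-139           0.0254      0.000638     3.57e-85
```

Read: 17 of 180 trials (9.4%) fail QC, matching the generator's ~10%
contamination. The short-latency CoP response shows no velocity dependence
(ANOVA p = 0.81, so the regression gate stays closed), while the
medium-latency response scales strongly with peak velocity — the recovered
slope 0.0254 ± 0.0006 (N/kg)/(deg/s) matches the generator's injected
`medium_vel_gain` of 0.025. That is the acceleration/velocity dissociation
the pipeline is built to detect.

```r
man$asymmetry$combined
#>    axis n_tests fisher_p
#> 1 pitch       9 0.902447
```

With the generator's default mirror-symmetric directions, the
Fisher-combined asymmetry p-value is far from significance, as it should
be.

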