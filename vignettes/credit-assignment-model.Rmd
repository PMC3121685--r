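---
title: "Modelling credit assignment in motor adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling credit assignment in motor adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the science it implements: the
state-space model of trial-by-trial motor adaptation, the two credit
assignment rules it compares, the closed-loop simulator and synthetic-data
generator, and the numerical and design decisions taken where the problem
was genuinely open.

## The task and its physics

Subjects make 10-cm point-to-point reaches in the horizontal plane. On
force-field trials a viscous curl field pushes on the hand with force
`F = B (v_y, -v_x)`, where `B` (N/(m/s)) is the signed field viscosity —
positive for a clockwise (CW) field, which deflects a reach toward smaller
movement angles. The force is orthogonal to the velocity at every instant,
so the field does no mechanical work; for a reach peaking at 0.3 m/s in the
`B = 9` field the peak perturbing force is 2.7 N.

Reference kinematics are fifth-order minimum-jerk profiles
(`min_jerk_trajectory()`), whose peak speed is `1.875 d/T`. The default
duration of 0.621 s makes a 10-cm reach peak at 0.302 m/s, the observed
mean peak speed of the task; the 500 ± 50 ms completion-time feedback given
to subjects is treated as task instruction rather than as the simulated
movement duration. Trajectories are sampled at 200 Hz (`dt = 0.005` s).

## The learning model

Adaptation is a function `x_n(θ)` over movement direction, held on a dense
wrap-aware grid covering [−180°, 180°) (1° steps by default). Its units are
compensated viscosity, N/(m/s), on the axis where **positive values are
compensation appropriate for the counter-clockwise field**; a subject fully
adapted to a field of viscosity `B` has `x = −B` at the trained direction.
This is the axis on which generalization patterns are conventionally
plotted, and it makes the error-clamp adaptation coefficient (below) come
out as `+1` at full compensation regardless of the trained field's sign.

After each force-field trial with directional error
`e_n = wrap(θ_actual − θ_planned)`:

```
x_{n+1}(θ) = A · x_n(θ) + e_n · k · exp(−(θ − θ_ref)² / 2σ²)
```

- Under **plan-referenced learning (PRL)** `θ_ref` is the planned
  direction (the target: plans are essentially straight for short
  reaches).
- Under **motion-referenced learning (MRL)** `θ_ref` is the actual initial
  movement direction.

Null-field and error-clamp trials update by retention alone: in a null
field the error carries no information about any force-field, and in the
clamp the lateral error is held to approximately zero. Because the
recursion is linear, the state after any history equals a geometric-decay
superposition of single-trial Gaussian increments; `closed_form_state()`
implements that superposition and serves as an independent oracle for the
iterated update in the test suite.

The model indexes primitives by the *initial* movement direction rather
than the full velocity time series. That approximation is good while
movements are approximately straight — which holds over the portion of the
reach where speeds, and hence viscous forces, are appreciable — and it is
what makes the state one-dimensional and the extremum analysis
deterministic.

## Parameters, defaults and where they come from

| parameter | default | units | rationale |
|---|---|---|---|
| retention `A` | 0.98 | per trial | typical of single-rate state-space fits to force-field adaptation; not pinned by any quantity the package reproduces (see the sensitivity note below) |
| gain `k` | 0.0357 | N/(m/s) per deg | set so one naive trial in the `B = 9` field yields ~5% of full compensation at the primitive centre |
| primitive width `σ` | 28.85 | deg | direction-space equivalent of a 0.12 m/s velocity-space primitive; see below |
| error gain `η` | 1.4 | deg per N/(m/s) | places the interference paradigm's mean CW/CCW direction separation near 25°; `calibrate_error_gain()` refines it to the anchor |
| motor noise SD | 3 | deg | trial-to-trial variability of the initial direction |
| `cw_gain_scale` | 1 | — | optional learning-rate asymmetry between field directions; off by default |
| grid step | 1 | deg | makes extremum-finding deterministic at the probe spacing used |

**The primitive-width conversion.** The primitive's width is known in
velocity space: σ_v = 0.12 m/s. Two conversions to direction space
present themselves. The chord subtended at peak speed,
`σ_v / v_peak ≈ 22.8°`, ignores that most of a reach is spent below peak
speed, where a given angular offset maps to a *small* velocity offset and
the primitive is therefore still strongly activated. The package instead
evaluates the activation of a primitive centred on one minimum-jerk
velocity path along a path rotated by Δθ (instantaneous separation
`2 s(t) sin(Δθ/2)`), averages it over the movement with speed-squared
weights — the part of the movement where velocity-dependent forces act —
and fits a Gaussian to the resulting direction-tuning curve
(`primitive_sigma_from_velocity()`), giving σ ≈ 28.9°. The distinction is
not cosmetic: with the chord conversion the interference simulation's
peak-to-trough separation comes out near 2 × 22.8 ≈ 46–48°, which is
incompatible with the ~60° separation the model is known to predict at
these error sizes, while the trajectory-overlap conversion reproduces it
with no free parameter. The width remains a configuration parameter for
users who want either convention.

**Retention sensitivity.** `A` mainly sets how much of the training
history the state remembers; the interference pattern's *shape* is set by
σ and the error distribution, and the paradigm orderings by the geometry
of the target shifts, so the package's headline quantities move little
over `A ∈ [0.95, 0.99]`. The parameter-recovery machinery
(`fit_learning_params()`) makes the choice non-load-bearing: the test
suite demonstrates that (A, k, σ) are recoverable within 10% from a
16-subject synthetic cohort.

## The closed loop

Each trial is summarized by one direction. On a curl trial the error is
`e = −η (B + x(θ_target)) + ε`, `ε ~ N(0, 3°)`: a naive subject in the CW
field errs toward smaller angles by `η B` degrees, and the error decays as
compensation builds. Null trials have pure-noise errors. Error-clamp
trials are idealized — lateral displacement exactly zero, so the actual
direction equals the planned one — rather than modelled as a stiff
spring-damper channel, which would introduce two unconstrained stiffness
parameters the analysis never uses. The clamp measurement is synthesized
from the state: the lateral force is `x(θ_probe) · s(t)` along the
reference speed profile, bell-shaped for minimum-jerk reaches, and the
**adaptation coefficient** is the no-intercept least-squares slope of that
measured profile on the ideal compensating profile `−B_ref · s(t)`. With
these conventions the coefficient is exactly `−x(θ_probe)/B_ref`, i.e. 0
for a naive and 1 for a fully adapted subject. The regression window runs
over the whole movement (speed above 5% of peak excludes only endpoints
where both profiles vanish, so the whole profile is used); whether the
original analyses included an intercept is unrecorded, and the
no-intercept convention is declared here once and used everywhere.

## Schedules

**Interference paradigm** (`interference_schedule()`): 254 null-field
baseline reaches over nine directions, then four segments of 168
force-field trials at the training direction, each followed by 40
consecutive error-clamp probes spread over the nine directions. Blocks
alternate CW/CCW "every 7 ± 2 movements" while the printed CW:CCW ratios
(7:7, 6:8, 5:9) are exact — two constraints that no published recipe
reconciles, so the package takes this reading: each 14-trial cycle pairs a
CW block of `ratio_cw + j` with a CCW block of `ratio_ccw − j` trials,
with `j` uniform on the largest range keeping both lengths in 5…9, and the
partner cycle negates `j` so the ratio is exact over every cycle pair. For
the 5:9 ratio the range collapses to `j = 0` and the counts are exact per
cycle. The field of the final block before each testing block alternates
(CCW, CW, CCW, CW), balancing the most-recent-field effect across the four
generalization measurements. The 254 baseline trials are spread as evenly
as possible over the nine directions (28 or 29 each) with a seeded
shuffle, and likewise the 40 testing trials (4 or 5 per direction); the
original per-direction apportionments are unrecorded.

**Shifted-target paradigms** (`shifted_schedules()`): 75 baseline + 125
training trials toward a desired learning direction (90°), error-clamp
probes at that direction interspersed with probability 0.2. STT presents
the target at 90° throughout; LST presents it at `90 − s_n` and RST at
`90 + s_n`, where `s_n` is a smoothed fit of the mean error history of a
pilot STT cohort — so LST targets sit opposite the expected error and the
actual motion lines up with 90°, while RST doubles the misalignment. With
the signed-error convention used here (CW errors negative), *subtracting*
the smoothed error implements what is verbally described as "adding" the
shift leftward. The probe placements are drawn once per call and shared by
the three schedules, pairing matched-seed comparisons. The smoothing
family is the two-parameter exponential `a·exp(−n/τ)` fitted by
least squares (`smooth_error_history()`), with a grid-plus-refinement
fallback that handles the constant-series τ→∞ limit. A limitation worth
knowing: when training errors decay toward a nonzero floor, a
two-parameter decay-to-zero model compensates with a large τ; in practice
the fitted shifts still align LST actual motion with the goal to within
2°, which is the property that matters and that the test suite checks.

**Experiment orchestration.** `run_exp2()` mirrors the original staging:
the shifts are calibrated from a simulated 17-subject STT pilot run under
MRL (the generating mechanism for behaviour in this framework), then the
same shift sequence serves all paradigms under both hypotheses, as it did
experimentally.

## The synthetic-data generator

`generate_subject()` wraps the closed-loop simulation and renders its
outcome as raw-looking data: per-trial movement durations
`N(0.621 s, 0.035 s)` (so peak speeds cluster at 0.302 ± ~0.017 m/s),
log-normal reaction times (median 0.3 s), optional full 200-Hz traces with
smooth 1-mm positional jitter (velocities recomputed from the jittered
positions, so trajectory invariants survive), and configurable
out-of-bounds outlier injection (default 1.5% each for peak speed and
reaction time, leaving ~97% of trials retained — comparable to the 94–98%
inclusion rates the filtering criteria produced experimentally).
`generate_cohort()` derives per-subject seeds from a master seed and
applies mild log-normal jitter (5% SD) to the learning and error gains.

The **impaired preset** (`subject_profile("impaired")`) halves the
learning gain and doubles the motor noise — slower learning and higher
residual errors, the signature reported for chronic stroke patients. The
exact factors are placeholders standing in for patient-literature values
the package does not have; the claims made of the preset are orderings
only: impaired cohorts show larger residual errors, and the relative
LST-over-STT advantage is larger early and persists later than in healthy
cohorts.

What the generator does *not* emulate — and therefore what passing tests
do not certify about real data: within-trial feedback corrections and
their late-movement velocity content, biomechanical anisotropies across
the workspace, the empirical CW-learning bias time course (only a static
`cw_gain_scale` is exposed), use-dependent learning, savings, and
inter-subject idiosyncrasies beyond scalar gain jitter.

## Numerical choices and degenerate inputs

- Angles live in (−180°, 180°]; all differences are wrap-aware. State
  reads use wrap-aware linear interpolation on the grid.
- `peak_separation()` interpolates patterns to a 0.5° grid, requires a
  positive maximum and negative minimum beyond a noise threshold (twice
  the pooled standard error when the pattern has one, else zero) and
  raises a no-bimodality error otherwise; exact ties break toward the
  training direction.
- `adaptation_coefficient()` refuses an identically zero ideal profile;
  `pattern_correlation()` refuses zero-variance patterns and fewer than
  three aligned probes; `learning_summary()` requires six probes.
- Inclusion bounds are strict inequalities; trials with missing
  kinematics are excluded and reported separately, never silently
  dropped.
- Simulations are deterministic given (schedule, parameters, seed): one
  seeded RNG stream per experiment, with per-subject seeds derived from
  the master seed.

## Problem sizes

The packaged analyses use 12-subject interference cohorts (matching the
original group size), 30-subject cohorts per training paradigm, a
17-subject pilot for shift calibration, and a 16-subject cohort for the
parameter-recovery demonstration; with the vectorized state update each of
these completes in about a second, and the full test suite in well under a
minute. Users exploring parameter space can scale any of these up through
the `n_subjects` arguments.

## Known limitations

- The one-dimensional direction-indexed state cannot express
  generalization across speeds or extents, only across directions.
- The error model is a static gain; reaction-time- or speed-dependent
  error modulation is not modelled.
- The clamp idealization removes channel-interaction artefacts that real
  force-channel data contain.
- Late-training "convergence" of the three paradigms is attenuation of
  the between-group spread within the 125-trial window, not equality;
  full equalization requires extended training.
- Statistics on the original human cohorts (correlations with measured
  generalization, group percentage effects) require the experimental
  data, which are not deposited, and are deliberately out of scope.
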