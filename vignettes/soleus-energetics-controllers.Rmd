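---
title: "Energetics-based ankle exoskeleton torque profiles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energetics-based ankle exoskeleton torque profiles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soleusExo)
```

## The problem

Powered ankle exoskeletons assist plantarflexion during gait. The best-known
way to choose the assistive torque profile — human-in-the-loop (HITL)
optimization — tunes a parameterized waveform per person and per task over
hours of metabolic measurement, and the result does not transfer between
tasks. An alternative is to derive the profile from the physiology that makes
plantarflexion expensive: the chemical energy spent by the soleus fascicles.
The soleus is uniarticular, dominates ankle plantarflexion, and works in
series with the Achilles tendon, which stores elastic energy in early stance
and returns it at push-off. Assistance should therefore concentrate where the
fascicles hydrolyse ATP fastest, and stay out of the way while the tendon is
being loaded.

`soleusExo` implements two such controllers and the machinery to evaluate
them. Inputs are gait-normalized curves — joint torque (Nm/kg), normalized
fascicle velocity and normalized tendon velocity (resting lengths per second,
`l0/s`) — either ingested from digitized tables or produced by the package's
synthetic generator.

## The ATP-hydrolysis-rate model

The energetic core is a saturating hyperbola of normalized fascicle speed
with the resting (zero-velocity) hydrolysis rate subtracted, so only the ATP
spent on motion remains:

$$ As(v) \;=\; \frac{M \, D \, v}{1 + D \, v}, \qquad v = |V_{CE}|/l_0 $$

`M` is the asymptotic rate at infinite velocity and `1/D` the speed at which
half of `M` is reached. Slow-twitch (type I) and fast-twitch (type IIA)
fibers have their own `(M, D)` pairs and are mixed by the soleus composition
`R_slow = 0.8`, `R_fast = 0.2`. The net rate of a muscle that can lengthen
and shorten is piecewise:

* zero wherever the muscle-tendon-unit (MTU) force `F` is negative (the
  muscle is unloaded in the assisted direction);
* `R_slow As_slow(|v|) + R_fast As_fast(|v|)` when the fascicle shortens
  (`V_CE <= 0`, concentric — `V_CE = 0` is assigned to this branch);
* the same mixture times an eccentric correction of `1/2.7` when the fascicle
  lengthens (`V_CE > 0`).

The `1/2.7` (velocity) and companion `1/3.6` (force) eccentric corrections
were measured at the knee-joint level, not for soleus fascicles; they are
configurable (`EccentricCorrections()`) and no attempt is made to improve
them.

### Fiber constants are configuration

The single-fiber `(M, D)` constants are mandatory configuration. The bundled
defaults (`inst/extdata/fiber_params_synthetic.yaml`: slow `M = 1, D = 4`;
fast `M = 3, D = 1.5`, arbitrary rate units) are this package's own
realistic choices — fast fibers have the higher asymptotic ATPase rate and
reach half of it at a higher shortening velocity — and are labelled synthetic
in the file itself. Absolute rate units are irrelevant to profile *shape*:
the peak-matching calibration constant absorbs them. They do affect the
relative weighting of slow vs fast fibers across the speed range, which is
one reason the bundled defaults cannot be expected to reproduce any
particular published waveform.

## The two controllers

**FS (force scaled)** multiplies the MTU force by the net rate:

$$ FS = C_F \cdot \begin{cases} 0 & F < 0 \\ F \cdot As_{net}(V_{CE}) & V_{CE} \le 0 \\ \tfrac{1}{3.6}\, F \cdot As_{net}(V_{CE}) & V_{CE} > 0 \end{cases} $$

`F` is the joint torque divided by a constant Achilles moment arm (4.2 cm,
the mean over 20–60% of the walking gait cycle; because `C_F` rescales the
result, a different constant arm changes only the scale factor, not the
shape). FS mimics the human torque weighted by where the muscle spends
energy.

**DB (deadbanded)** uses the rate alone, with the fascicle-speed deadband set
at the instant the tendon reaches its maximal lengthening velocity. The
fascicle speed observed at that instant becomes a threshold `v*`; all speeds
at or below it are treated as zero and the hyperbola is shifted to restart
from zero:

$$ As^{shifted}(v) = \frac{M D \max(v - v^*, 0)}{1 + D \max(v - v^*, 0)} $$

and `DB = C_shifted ·` (the same force-sign-gated, eccentric-corrected
mixture, with `As^shifted` in place of `As`). The deadband operates on the
speed `|V_CE|`, while the *sign* of `V_CE` still selects the eccentric
branch — this keeps lengthening phases energetically discounted exactly as in
the direct model. DB needs no force magnitude at all: only the sign of `F`
enters.

Ties at the tendon-velocity maximum break to the earliest sample
(first-attainment reading of "reaches its maximal lengthening velocity"); an
all-nonpositive tendon-velocity trace is degenerate input and yields a
warning plus the least-negative sample.

### Calibration

Both controllers are produced uncalibrated (arbitrary units) and peak-matched
to a reference peak magnitude at one anchor speed per gait type — 1.4 m/s for
walking, 3.0 m/s for running. The anchor's scale factor (`C_F`, `C_shifted`)
is then reused unchanged at every other speed of that gait, so across-speed
magnitude changes are a genuine prediction of the model, not of the
calibration. A speed-continuous `C` is deliberately not implemented.

## Axes, grids and sign conventions

* Percent axes are 0-based and inclusive of both ends; 101 points give exact
  1% spacing. Resampling is linear, with endpoint hold outside the source
  range (the curves are smooth at 1% resolution, so nothing fancier is
  warranted).
* Velocities are lengthening-positive everywhere; digitized sources with the
  opposite convention are negated at ingestion (`negate = TRUE`).
* Stance-only data are mapped to the gait cycle by scaling the phase axis so
  100% stance lands at toe-off. The walking default is 62.7% gait (the mean
  offset timing of the walking HITL reference study at 1.25 m/s); it is a
  per-condition configuration value because a speed-dependent toe-off may be
  preferable, a question we leave open. Walking key points are reported in
  percent gait, running in percent stance, and the comparison functions
  refuse to mix phase kinds.

## Reference profiles

HITL-style references are rebuilt from their four parameters (onset, peak,
offset timing; peak torque) plus the small pre-onset cable-tensioning torque
reached by a linear ramp from the start of the cycle. The rise and fall
"spline" family of the original studies is not published; this package uses
cubic smoothstep segments — monotone, zero slope at each segment end — which
guarantee continuity, no overshoot, and a maximum exactly equal to the peak
parameter. This is a reconstruction choice, flagged as such.

Envelopes take the pointwise min/max across per-subject curves; the
mean-parameter curve is included among the extrema, because when subjects'
peak timings straddle the mean timing the mean-parameter curve can otherwise
poke above the pointwise subject maximum. "Estimated optimum" (EO) parameter
sets are obtained by interpolating each parameter linearly in speed between
anchors; extrapolation beyond the anchor range is off by default and warns
when enabled, since it extends the cited interpolation scheme.

The bundled reference parameter files are synthetic stand-ins: the published
key-point min/max ranges (and the 62.7% mean offset) are used where printed,
mean timings are range midpoints, and the peak torques and per-subject sets
are realistic constructions. The files say so in their headers.

## Comparison measures

* **Key points.** The threshold is a fixed fraction of the profile's own peak
  (3.9% walking, 8.8% running — the average HITL onset torque as a percent of
  peak). Onset is the *last* up-crossing at or before the global peak
  (earliest sample on peak ties), offset the first down-crossing after it;
  crossings are interpolated between samples, not snapped to 1% bins. The
  last-up-crossing rule anchors onset to the main lobe, so the early-stance
  bump DB develops at fast running cannot masquerade as onset. Because the
  threshold is relative, timings are invariant under calibration.
* **Cosine similarity.** Profiles resampled to 101 stance points are treated
  as vectors; the cosine of their angle is reported (1 identical direction,
  0 orthogonal).
* **Discrete Fréchet distance.** Computed by the standard dynamic-programming
  recurrence over the coupling lattice on 2-D points (phase in percent,
  torque in Nm/kg) with the Euclidean metric and no axis normalization —
  raw mixed-axis coordinates match the magnitude of published distances; an
  axis-weight option (default `c(1, 1)`) is exposed. The test suite checks
  the recurrence against an exhaustive enumeration of monotone couplings for
  curves of up to 7 points.

## The synthetic generator

`synthDynamics()` builds dynamics from raised-cosine bumps (smooth, compactly
supported, analytically evaluable, so tests can plant features and recover
them in closed form): a unimodal torque bump with a small dorsiflexion dip
after heel strike (exercising the `F < 0` branch), early-stance tendon
lengthening followed by recoil, a broad slow-shortening fascicle plateau
through mid-stance (which puts a nonzero fascicle speed under the tendon
peak, hence a nonzero deadband threshold), a fast late-stance shortening
bump, and an optional early-stance secondary mode. Defaults scale with gait
type and speed: the walking set is 0.7/1.4/2.0 m/s and the running set
2.0/3.0/4.0/5.0 m/s, with the secondary fascicle mode on at the two fastest
running speeds, where it produces the early-stance DB lobe. All randomness
(additive Gaussian noise, off by default) flows through the single explicit
seed in `SynthConfig`; the global RNG state is untouched.

What it emulates is morphology, not values: curves return to near zero by
toe-off, peaks sit in realistic phase regions, magnitudes grow with speed.
What it does not emulate: subject variability, measurement noise structure of
ultrasound feature extraction, pennation effects, or the actual digitized
waveforms of any study. Passing tests on these fixtures therefore demonstrate
that the *machinery* is correct (branch tables, deadband logic, calibration,
metrics), not that the package reproduces any particular published table —
reproducing published key points requires the original digitized curves and
the original fiber constants as inputs.

```{r example}
dyn <- synthDynamics(SynthConfig("walk", 1.4))
cfg <- defaultControllerConfig("walk")
db <- deadbandSpeed(dyn)
db
fs <- calibrate(fsProfile(dyn, cfg), 0.55)
keyPoints(stanceToGait(fs, 62.7), cfg@onsetFraction)
```

## Problem sizes and numerical choices

All pipelines run on 101-point grids (1% increments); the full test suite,
including a 1000-trial brute-force Fréchet oracle and the end-to-end walking
and running condition sets, completes in well under a minute on one CPU.
Other numerical decisions, collected:

* `V_CE = 0` sits on the concentric branch; since `As(0) = 0` the net rate is
  continuous at zero velocity despite the branch switch (asserted in tests).
* The assistive-torque construction is nonnegative by algebra (all surviving
  branches are products of nonnegative factors); an assertion, not a clamp,
  guards this.
* Calibration of an all-zero profile, key points of a non-positive profile,
  and cosine similarity against an all-zero profile are explicit errors, not
  NaNs.
* Reports print timings to one decimal place; the YAML artifacts keep full
  precision. Every artifact records an md5 hash of the run configuration and
  `runCompare()` refuses profiles generated under a different hash.

## Limitations

* Single-muscle model: no gastrocnemius (its late-stance contribution would
  plausibly delay offsets at running speeds), no pennation, uniform fiber
  recruitment.
* No swing-phase modelling; controllers output zero outside the data's phase
  range by construction.
* No hardware or closed-loop control: the deliverable is torque-vs-phase
  lookup profiles plus comparison reports.
* The bundled fiber constants and reference parameter sets are synthetic
  stand-ins, as described above; all of them are plain editable files meant
  to be replaced by measured values.
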