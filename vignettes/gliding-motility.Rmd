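---
title: "Gliding motility kinematics and spiral formation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gliding motility kinematics and spiral formation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The system

Filamentous cyanobacteria of the *Phormidium* type glide over agar
surfaces without flagella, propelled by mucilage secreted from rows of
junctional pores beside each septum.  On a plate a filament moves back and
forth with a period of roughly 5–10 minutes, leaving behind a fibrous
sheath that guides later passes, and populations of filaments organize
into macroscopic, continuously rearranging structures — meshworks, bundles
and, on sufficiently solid agar, counterclockwise spirals.

`glidekin` provides three connected layers:

1. **kinetics** — a closed-form post-reversal speed law and its
   cycle-average identities;
2. **measurement** — a pipeline from a tracked tip trajectory to signed
   velocities, reversal cycles, decay-law fits (`fit_decay()`, the
   package's central model object), pooled speed distributions and
   condition comparisons;
3. **simulation** — a rule-based 2-D plate model in which trail guidance,
   fixed-handed curvature and left turns at encounters let spirals emerge,
   plus seeded generators that stand in for time-lapse recordings.

# The speed law

The tip speed is maximal immediately after each reversal of direction and
declines exponentially to a terminal value:

$$v(t) \;=\; v_\mathrm{term} + (v_\mathrm{max} - v_\mathrm{term})\,
  e^{-t/\tau},$$

with $t$ the time since the last reversal.  This offset exponential is the
minimal law consistent with a burst-then-decline of propulsion, as
predicted by the slime-gun picture (secretion pressure is highest just
after the active pore row switches, then relaxes); we deliberately do not
model the nozzle hydration/ejection physics itself.  Power-law or other
decline shapes are out of scope.

Averaging over a cycle of duration $T$ gives

$$\bar v(T) = v_\mathrm{term} + (v_\mathrm{max} - v_\mathrm{term})
  \frac{\tau}{T}\left(1 - e^{-T/\tau}\right),$$

which is affine in $v_\mathrm{max}$ and therefore invertible in closed
form (`solve_vmax_for_average()`).

## Anchor parameters and units

Two measured conditions anchor the package defaults:

| condition | $v_\mathrm{term}$ (µm/s) | $\tau$ (s) | mean speed (µm/s) | $v_\mathrm{max}$ (µm/s, derived) |
|-----------|-----|-----|-------|-------|
| 1.5% agar | 0.169 | 99  | 0.216 | 0.385 |
| 2.0% agar | 0.148 | 108 | 0.162 | 0.207 |

The post-reversal maximum is not directly reported anywhere, so it is
*derived*: we fix it by requiring the cycle average at the reference
duration $T = 450$ s (the midpoint of the 5–10 min reversal range) to equal
the measured condition mean.  Note a units subtlety in the source data:
time constants of an exponential decline are printed with reciprocal-second
units, but dimensionally the e-folding constant of $e^{-t/\tau}$ is a time;
we interpret 99 and 108 as seconds throughout, and flag rather than
silently convert.

`agar_to_params()` interpolates $v_\mathrm{term}$, $\tau$ and the mean
linearly between the anchors (extrapolating with clipping at physical
bounds), and marks concentrations below 1.1% as *submerged*: there the
filaments sink into the gel, spread diffusely and never form spirals, so
the simulator still runs but spiral classification is disabled rather than
pretending to model three-dimensional intrusion.

We read the 5–10 min "period" as the reversal-to-reversal interval (not a
full back-and-forth cycle): with $\tau \approx 100$ s the decline
essentially reaches its terminal value within such an interval, which is
what the velocity traces show.  Intervals are drawn independently per
cycle from $U(300, 600)$ s; no refractory coupling is modelled because
only the range is known.

# The measurement pipeline

`analyze_track()` chains the steps applied to each track
(`frame,time_s,x_um,y_um` CSV):

* **Signed 1-D coordinate.**  A back-and-forth tip track folds onto its own
  path, so we project onto the *path tangent*: the tangent at each sample
  is estimated by principal-component analysis of the positions in a
  sliding window (default 9 frames), its orientation is made continuous in
  time, and frame-to-frame displacements are accumulated along it.
  Doubling back flips the sign of the projection, never the tangent, which
  makes the construction robust to tracking noise; naive schemes based on
  consecutive displacement directions flip spuriously as soon as the
  per-frame noise is comparable to the per-frame displacement.  For
  quasi-straight tracks the coordinate reduces to signed distance from the
  reference point; the arc-length formulation generalizes to curved,
  sheath-guided tracks.
* **Velocity** by central differences (one-sided at the ends), with an
  optional moving-average smoother, default window 3 frames.
* **Reversals** at sign changes of the smoothed velocity that exceed a
  hysteresis of 0.02 µm/s on both sides (the data are silent on noise
  handling; both the window and the hysteresis are exposed).  Reversal
  times are interpolated at the zero crossing.
* **Cycles** between consecutive reversals; partial head/tail stretches are
  excluded because their decay phase is unanchored.  Speed samples within
  2 frame intervals of either reversal are also excluded from the fit
  samples: a central difference plus a 3-frame smoother straddles the
  reversal there and mixes opposite-direction motion, which otherwise
  biases $\tau$ upward by ~15%.  The excluded band still contributes to
  the displacement integral.
* **Decay fit** (`fit_decay()`): bounded Levenberg–Marquardt least squares
  of the speed law on (time-since-reversal, speed) pairs, pooled across
  cycles (or per cycle, averaged).  Bounds $v_\mathrm{term} \ge 0$,
  $v_\mathrm{max} \ge v_\mathrm{term}$,
  $\tau \in (0, 10\,\max T]$; initialization at the minimum speed, the
  maximum speed and a third of the mean duration.  Essentially constant
  speed data leaves $\tau$ unidentifiable; this sets a `converged = FALSE`
  flag instead of raising.
* **Distributions**: absolute speeds pooled over all time points,
  summarized on linear and log10 scales (log10 is a presentation choice).
  Zero speeds are excluded from log statistics and counted.
* **Condition comparison**: the source analysis reports significance at
  the 5% level without naming a test.  We default to Welch's $t$ on log
  speeds — the distributions are log-normal-like with very unequal sample
  sizes — with the Mann–Whitney test as an option.
* **Displacement–duration table**: the per-cycle upper limit slope is the
  maximum of displacement/duration; constant-speed cycles sit on that
  line, decaying ones below it.  For these per-cycle quantities "average
  velocity" means net displacement over cycle duration; the pooled
  condition means use mean $|v|$ over all time points.
* **Length–velocity saturation**: the observation is only that net
  velocity rises to an asymptote with filament length, so the saturating
  form $v_\mathrm{net}(L) = a(1 - e^{-L/\lambda})$ is our choice of
  minimal two-parameter model; $\lambda$ at its lower bound (constant
  data) is flagged.

```{r}
library(glidekin)
st <- generate_track(track_gen_config(duration = 9000, seed = 1))
fit <- analyze_track(st$track)$fit
print(fit)
plot(fit)
```

# The plate simulator

Each filament is a polyline agent whose centreline always lies along the
sheath trail it has deposited.  Internally the trail is a single
arc-length-parameterised path of straight segments (default 2 µm) and the
body occupies a sliding interval on it; gliding translates the interval,
so retracing the sheath is exact by construction and body arc length is
conserved to machine precision — growth is the only operation that changes
it.  The rules per time step:

* speed from the decay law at the filament's phase since its reversal;
* within the stored trail, the filament simply follows it ("the sheath
  guides"); trail-following overrides curvature entirely;
* past the end of the trail — virgin substrate — new trail is laid down,
  turning at $\kappa$ rad/µm (default 0.002, a modelling parameter, not a
  measured one) and depositing trail points with radius width/2 (default
  width 5 µm);
* a foreign trail or body within its deposit radius blocks the way; the
  advancing tip turns counterclockwise ("left") in 5° increments up to
  170°, after which it stalls for the step — a valid outcome;
* scheduled reversals flip the travel direction, reset the phase and draw
  the next interval; growth multiplies length by
  $2^{\Delta t / T_\mathrm{double}}$, appended equally at both ends (the
  data are silent on end bias; it is configurable).

The time step must satisfy $v_\mathrm{max}\,\Delta t <$ deposit radius so
a step cannot jump a trail; the default $\Delta t = 5$ s satisfies this
for all surface conditions.

## Chirality

The planar model collapses the filament's axial rotation and the helical
mucilage flow into the single curvature rate $\kappa$,
counterclockwise-positive.  One subtlety matters: the curvature sign is
fixed in the filament's *body frame* (its anatomical chirality), not
relative to the instantaneous direction of travel.  Extension at either
end turns the path tangent the same way as a spatial curve.  Had we
applied "turn left of motion" at both ends, the two ends would curve with
opposite spatial handedness and filaments would develop S-shapes with
zero mean winding; with body-frame chirality every filament curls with one
handedness, which is what plates show (uniformly counterclockwise curving
filaments, counterclockwise spirals).  Encounter turns, by contrast, are
genuinely left-of-motion for the advancing tip.

Spirals are classified from the body polyline: total signed turning
(winding) of at least $2\pi \times$ `min_turns` (default 2) *and* a
point-set diameter below half the arc length (a wound-up body is compact
relative to its length).  The diameter is computed as the maximum pairwise
distance over the convex hull — a lower bound on any enclosing-circle
diameter that is exact enough for a compactness test.  Windings are
reported for every filament even on submerged substrates, but
classification is disabled there.

How a spiral *initiates* is left open by the observations; the simulator
implements the stated movement rules and reports emergent outcomes without
asserting a unique mechanism.  Foreign sheaths act as obstacles by
default; a guide mode (bundling) would be a separate behaviour and is not
modelled.  Intra-filament non-uniform motion (different parts of one long
filament moving oppositely) is outside the default model: per-filament
motion is synchronous along the polyline.

```{r}
sc <- list(agar = 1.5, duration_s = 150000, dt_s = 5,
           doubling_time_s = 21600, seed = 11, encounters = TRUE,
           inoculum = list(list(x_um = 0, y_um = 0, heading_rad = 0,
                                length_um = 100)))
state <- simulate_plate(sc)
detect_spirals(state)
plot(state)
```

# Synthetic data: what it does and does not emulate

The generators replace unavailable time-lapse recordings and define the
conditions under which the package tests itself:

* `generate_track()` integrates the decay law along a constant-curvature
  path with scheduled reversals and adds i.i.d. Gaussian position noise,
  default SD 0.05 µm per coordinate — well below the ~0.2 µm per-frame
  displacement at 1 s intervals, a plausible tracking error for
  sub-micrometre centroid localization.
* `generate_speed_samples()` emulates pooling "over all time points" of a
  fixed-rate video: cycle durations are drawn length-biased (longer cycles
  contribute more frames), observation times uniformly within the cycle.
  A mean-preserving multiplicative log-normal noise with CV 0.15 (default)
  represents measurement scatter; it is what gives the pooled distribution
  its smooth log-normal-like tails, since the noise-free law has hard
  support $[v_\mathrm{term}, v_\mathrm{max}]$.
* `generate_plate_scenario()` emits plug, sparse and two-filament-encounter
  inocula.

What passing tests therefore show: the pipeline recovers the parameters
of data *with this structure* (exponential decay, uniform reversal
intervals, Gaussian/log-normal noise) at realistic noise levels and sample
sizes.  What they cannot show: robustness to segmentation artefacts,
frame drops, drift, filament crossings in the raw imagery, or deviations
of real speed decays from a single-exponential form.

# Problem sizes and numerical choices

The test and acceptance workloads are desk-scale by design: decay-law
recovery uses ~200 cycles per condition (ten 2.5 h tracks at 1 s frames);
pooled mean checks use $2 \times 10^4$ samples; the condition-separation
check uses the published pooled sizes $n = 8882$ and $1397$; spiral
emergence uses one filament with an accelerated 6 h doubling time for
~1.7 simulated days (about seven doublings, standing in for 16 days of
plate growth at realistic division rates); the radial-spread contrast uses
ten replicate 12 h plug plates of 8 filaments per condition.  All
randomness flows from explicit seeds; rerunning any generator or
simulation with the same configuration is bit-reproducible, and generator
draws restore the caller's RNG state.

Known limitations: the plate boundary is recorded but not enforced (desk
scales stay far from it); filament breakage and death are not modelled
(filament count is non-decreasing); mechanical bending elasticity,
nutrient and light fields, mucilage hydrodynamics and three-dimensional
biofilm structure are all out of scope.
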