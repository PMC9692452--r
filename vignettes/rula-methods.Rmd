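---
title: "Automated RULA from multimodal skeleton tracking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated RULA from multimodal skeleton tracking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ergorula)
```

## The assessment problem

RULA (Rapid Upper Limb Assessment) scores a worker's posture into a 1–7
grand score by banding joint angles per body segment, combining the arm and
wrist branch (section A) and the neck/trunk/legs branch (section B) through
published lookup tables, and mapping the grand score to one of four risk
levels. Observational RULA leaves the wrist to the assessor's eye; this
package instead computes all wrist kinematics from a hand-tracking sensor
(25 joints per hand at a nominal 64 Hz) and the body segments from a
body-tracking sensor (16 joints at 30 Hz), fusing the two streams onto a
common 20 Hz grid.

The pipeline is: read streams → rate-balance with Piecewise Aggregate
Approximation (PAA) → fuse by nearest grid timestamp and attach activity
labels → drop frames with a missing scoring joint → calibrate the wrist →
score every frame → optionally compare against expert labels and across
subjects.

## Rate balancing with PAA

For a univariate series of length $n$ reduced to $N$ segments, PAA replaces
each segment by its mean:

$$\bar{x}_i = \frac{N}{n}\sum_{j = \frac{n}{N}(i-1)+1}^{\frac{n}{N} i} x_j.$$

Each joint coordinate channel (a joint's x, y or z) is reduced
independently. When $n$ is not divisible by $N$ we use the half-open index
windows $[\lceil (i-1)n/N \rceil, \lceil i n/N \rceil)$, which reduces to
the equal-block formula in the divisible case and loses no frames. Missing
values are excluded from a segment's mean; a fully missing segment stays
missing so the null-row filter still sees the dropout. Output timestamps
are segment-center times on the uniform grid (`grid_alignment = "center"`;
start-alignment would shift every timestamp by half a step and nothing
downstream depends on the choice, but center alignment keeps the
resampled sample closest in time to the data that produced it).

## Geometry kernel

Four constructions cover every scoring formula (degrees throughout, since
every published threshold is printed in degrees):

* `vector_angle(a, b)` — $\theta = \arccos\!\big(a\cdot b/(|a||b|)\big)$,
  with the cosine clamped to $[-1,1]$ so finite inputs never produce NaN;
* `three_point_angle(a, b, c)` — the angle between chain vectors $b-a$ and
  $c-b$ (a straight continuation reads 0; this is the supplement of the
  interior angle at $b$);
* `normal_vector(a, b, c)` $= (b-a)\times(c-a)$;
* `plane_angle(n_1, n_2)` — the angle between two plane normals.

Collinearity is flagged at a relative tolerance of $10^{-9}$: true
collinearity is measure-zero under sensor noise, but synthetic fixtures
can hit it exactly.

## Wrist kinematics

All wrist quantities come from five hand joints per side: the thumb
metacarpal endpoint (04), the index distal-phalanx start (05), the middle
proximal-phalanx endpoint (13), the middle metacarpal endpoint (14) and
the pinky metacarpal endpoint (24).

**Calibration.** The first frame in which those joints are present
supplies, per side, the neutral (handshake-pose) palm-plane normal
$NV(x_{13}, x_{04}, x_{24})$ and the neutral radial–ulnar chain angle.
Both anchor all per-frame measurements; the policy is configurable
(`first_valid` or a forced frame index).

**Flexion–extension** is, in the default `literal` mode, the angle between
the position vectors of joints 13 and 14 — the two-point form exactly as
the method defines it. Because two position vectors depend on where the
sensor origin sits, a `recentered` mode first translates both points so
the wrist reference joint (00) is the origin; both modes are tested. The
up/down sign is the sign of the x13 component along the calibration
normal; how the neutral "up" direction is fixed is not prescribed by the
method, so this is a documented interpretation.

**Radial–ulnar deviation** is the absolute difference between the current
chain angle through (05, 04, 24) and the same angle at calibration. The
raw chain angle at a neutral wrist is far from zero (about 90 degrees on a
real hand), so only the deviation from the calibrated neutral makes the
published 15-degree "bent from midline" threshold meaningful.

**Pronation–supination** is the angle between the current palm-plane
normal and the calibration normal. The arccosine folds rotations past
180 degrees back into $[0, 180]$ (a 200-degree physical rotation reads
160), which cannot be avoided without an orientation reference the
formulas do not provide.

**Scores.** The wrist position score is 1 inside a neutral band around 0
(default half-width 1 degree — the published band is the single point
"0°", which sensor noise would never hit), 2 up to 15 degrees up or down,
3 beyond, plus 1 when the deviation reaches 15 degrees, capped at 4. The
twist score is 1 in mid-range and 2 past 105 degrees; values below the
printed 75-degree band edge and above 165 map to the nearest band so the
score is total on $[0,180]$ with the published $\{1,2\}$ codomain.

## Body posture

Body formulas reference joints by two-digit tokens (01 head, 02 neck,
03 torso, 04 waist, 05/06 hips, 07–09 right arm, 10–12 left arm; the
registry is overridable because the sensor vendor's joint table is not
public, and token 19 — used only by the left shoulder-raise formula — is
an alias defaulting to the left shoulder).

A single angle convention does not make all printed bands coherent, so the
package fixes one per formula and documents it:

| measure | construction | neutral reads |
|---|---|---|
| upper-arm position | interior angle at the shoulder between elbow and hip directions, signed anterior/posterior | ~0 hanging |
| shoulder raised | interior angle at the neck between waist and shoulder directions, fires > 90 | < 90 |
| abduction | \|chain angle − 90\| | ~0 |
| lower-arm position | chain angle (flexion from a straight arm) | 0 straight |
| across midline | chain angle through the torso, fires > 90 | well below 90 |
| out to side | the upper-arm position angle, fires > 30 (the printed criterion reuses those joints) | ~0 |
| neck position | chain angle head–neck–waist, signed | 0 upright |
| neck side-bend | 90 − chain angle through the left shoulder | 0 |
| trunk position | 180 − angle(waist→head segment, vertical axis) | 0 upright |
| trunk side-bend | \|chain angle waist–hip − 90\| | 0 |
| trunk twist | \|angle(hip→waist vector, neck/hips plane normal) − 90\| | 0 |

The $|\cdot-90|$ pattern for the lateral adjustments mirrors the method's
own printed neck side-bend form ($90 - \angle(10,02,01)$); banding the raw
chain angle instead would fire those adjustments on every neutral standing
pose. Signs for the upper-arm and neck flexion bands come from projecting
the distal joint onto the body's anterior axis, estimated per frame as
the cross product of the trunk-up vector (waist→neck) and the hip-to-hip
vector; without a sign the printed negative bands would be unreachable.
Band edges are lower-inclusive/upper-exclusive, with strict inequalities
kept where the published criteria print ">". Exact-zero bands ("+1 (0°)")
use the shared 1-degree neutral band. The legs score is the protocol
constant 2 (standing, unsupported); muscle-use and force scores are fixed
at 0, and neck twist is not assessed.

A degeneracy worth knowing: the printed trunk-twist construction compares
the hip→waist vector with the normal of the plane through the neck and
both hips. That plane always contains the hip–hip line, so the measure is
insensitive to genuine axial trunk rotation; it responds only to
configurations that move the neck off the hip–waist plane. The package
computes it as printed (neutral-shifted so an upright stance reads 0), but
the synthetic generator refuses nonzero trunk-twist targets rather than
pretending to realise them, and the band-recovery sweep excludes that row.

## Score combination

The published RULA tables are embedded as constants (transcribed from the
standard worksheet), checksummed, and audited at package load for
monotone non-decrease in every argument — they are fixed published
constants, not free parameters. Section A is looked up per side from
(upper arm, lower arm, wrist position, wrist twist); section B once from
(neck, trunk, legs). Three grand scores are computed: left, right, and a
general score from the "Max" rule. The Max is applied per component
before the Table A lookup (not to the looked-up A scores), which places
the maximum upstream of the table and — by table monotonicity —
guarantees the general grand score dominates both sides; the per-A
alternative is available as `engine$max_mode = "per_A"`. Grand scores map
to risk as 1–2 negligible, 3–4 low, 5–6 medium, 7 high.

## Evaluation statistics

Agreement with expert labels uses
$\mathrm{numSim}(es, ss) = 1 - |es-ss|/(es+ss)$ averaged over aligned
pairs (tsim), stratified by segment, side and high-level activity; strata
with no labelled rows are absent from the report rather than fabricated.
Expert labels apply to their own fused row only (stride 10 by default,
i.e. one labelled row per 0.5 s); no forward fill is invented.

Across-subject comparison runs a one-way ANOVA on the general grand score
grouped by subject, then all pairwise two-sided two-sample t-tests.
Student's equal-variance test is the default as the classical companion
of the one-way ANOVA (the method's test variant is unstated); Welch is a
flag away. No multiplicity correction is applied by default, matching the
method's presentation; Holm/Bonferroni are available. Tests pool all
frames rather than per-activity means — the alternative aggregation is
one `split()` away from the same interface.

## The synthetic-data generator

Because the original recordings are not public, every stage is validated
on generated sessions. The generator emulates exactly the study's data
shape: a 30 Hz body stream and a 64 Hz hand stream with per-joint 3D
coordinates, occasional whole-joint dropouts, and three-level activity
labels (five high-level assembly steps, free mid-level text, six Therblig
low-level motions).

Joints are placed by forward construction on a canonical stick figure
(fixed limb lengths; all scoring is angle-based so the lengths are
arbitrary constants, with hips level with the waist so the lateral trunk
measures read 0 in the neutral stance). Each targeted formula is realised
exactly: closed forms where available (shoulder elevation, trunk
side-bend), otherwise a bracketed root solve on the one free azimuth per
limb, to within $10^{-6}$ degrees. Conflicting targets — for example an
abduction angle larger than the upper-arm cone allows, or a wrist
flexion/pronation pair whose rotation would flip the flexion sign —
raise a feasibility error listing the conflict instead of silently
approximating. Angular jitter is applied as small random rotations of
each joint about its parent, propagated down the kinematic chain so limb
lengths are preserved; dropouts are per-joint Bernoulli nulls. All
randomness flows from a single seed.

Sessions prepend a 0.5 s neutral handshake segment by default so the
pipeline's first-valid-frame calibration observes a genuinely neutral
wrist, mirroring the initial-position protocol.

What passing on synthetic data does and does not show: the fixtures
prove the geometry, banding, table combination, fusion arithmetic and
statistics are implemented exactly; they do not emulate sensor-specific
artefacts (occlusion-correlated dropouts, per-joint noise anisotropy,
clock drift between sensors), so field accuracy against a human assessor
cannot be inferred from them.

## Numerical choices and problem sizes

Angle solves use `uniroot` at tolerance $10^{-12}$ after a 121-point
bracket scan, with a minimisation fallback for targets at the boundary of
the achievable set (an unsigned angle hitting exactly 0). Collinearity
tolerance is $10^{-9}$ relative; arccos inputs are clamped. Test sessions
are a few seconds long (tens of fused frames) and the null-calibration
simulation uses 1,000 ANOVA replicates of four 30-frame subjects — sizes
chosen so the whole suite exercises every code path with sub-minute
stages while keeping Monte-Carlo error small.

## Known limitations

* The sensor vendors' joint tables are not public; the default registries
  are documented interpretations and fully overridable.
* The literal flexion–extension mode is origin-dependent by construction;
  the recentered mode is the physically meaningful variant.
* The printed trunk-twist formula cannot detect axial rotation (above).
* Scores for pronation–supination below the printed 75-degree band edge
  map to 1; whether they should ever exceed 1 is not derivable from the
  published bands.
* No gap interpolation, smoothing or time-offset estimation beyond PAA is
  performed; streams are assumed to share a clock.
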