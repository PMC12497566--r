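---
title: "Estimating instantaneous hip-extensor moment arms and strains from bone geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating instantaneous hip-extensor moment arms and strains from bone geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(momarm)
```

## The model

A muscle's capacity to rotate a joint is summarized by its *instantaneous
muscle moment arm* (IMMA): the perpendicular distance from the muscle's line
of action to the joint's center of rotation at a given pose. For unit muscle
force the IMMA equals the torque produced about the joint; a long arm favors
torque, a short arm favors rotational velocity. Whether that torque can
actually be produced depends on the muscle *strain* — the instantaneous
length as a fraction of resting length — since force generation plateaus
near resting length (taken here as the inclusive 85%–115% band).

`momarm` computes both quantities for the five principal hip extensors of a
small-bodied primate hindlimb (the uniarticular gluteus medius and minimus,
and the biarticular biceps femoris, semimembranosus and semitendinosus) from
segmented 3D bone geometry, under four modeling commitments:

1. **Joint center.** A sphere is fitted to femoral-head surface points by
   linear (algebraic) least squares; its center approximates the hip center
   of rotation. The linear formulation is deterministic, needs no starting
   value, and recovers exact spheres to machine precision. A geometric
   (nonlinear) refinement exists but differs only at high noise; it serves
   as an independent oracle in the test suite, not as the estimator.
2. **Line of action.** Each muscle acts along the straight segment joining
   the unweighted centroids of its origin and insertion attachment patches.
   No via points or wrapping surfaces are modeled.
3. **Kinematics.** The reference pose has 90° at hip and knee and defines
   every resting length. A pose at hip extension angle θ rotates the femur
   and shank rigidly together by (θ − 90)° about the flexion–extension axis
   through the hip center, so the knee stays locked at 90°. The standard
   sweep covers 20°–160° in 10° steps; angles outside that range are
   permitted with a warning.
4. **Projection and normalization.** The 3D arm is the distance from the hip
   center to the nearest point on the line of action. Because an oblique
   muscle also contributes to abduction and long-axis rotation, the reported
   arm is restricted to the parasagittal flexion–extension plane by
   projecting the moment-arm *vector* onto that plane (the default); two
   alternatives — projecting the whole line of action before measuring, and
   the torque-about-axis scalar — are available, and all three coincide for
   planar geometry. Lengths and arms are divided by body mass^0.33 for
   cross-specimen comparison (0.33 as conventionally printed, not 1/3;
   configurable).

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| sweep angles | 20–160 by 10 | deg | hip extension range, knee fixed at 90° |
| `clamp` | `TRUE` | — | nearest point on the attachment segment vs the infinite line |
| `projection` | `"vector"` | — | how the arm is restricted to the parasagittal plane |
| `exponent` | 0.33 | — | body-mass normalization power |
| strain band | 85–115 | % | inclusive optimal length–tension range |
| `sigma_mm` | 0.5 | mm | placement-repeatability jitter |
| mass / shift fractions | ±0.10, ±0.20 | — | perturbation levels of the robustness analyses |

### Segment versus infinite line

The `clamp` choice deserves a note, because for a straight chord rotating
rigidly about the same center used for the measurement the two conventions
differ *structurally*, not just numerically. Write β for the angle subtended
at the center between the origin and the (rotating) insertion. The
perpendicular distance of the center from the infinite line rises with β up
to a peak of min(ρ, R) (ρ, R the two attachment distances from the center)
and falls back toward zero as the chord sweeps through the center; the peak
occurs exactly where the perpendicular foot reaches the nearer attachment.
Clamping to the segment therefore replaces the entire far side of that bell
with a constant plateau at min(ρ, R): a clamped arm can only rise to a
plateau (or fall, or form a V) — it can never show a strict interior
maximum. Consequences:

* The segment-clamped arm (the default, mirroring how a nearest-point query
  on a finite muscle curve behaves in animation software) is the honest
  reading of "distance to the muscle", but near full extension it saturates
  at the attachment radius.
* For interpreting curve *shapes* — in particular the bell-shaped biarticular
  arm with its maximum near the reference pose — the infinite-line arm
  (`clamp = FALSE`), which is the physically conventional moment arm, is the
  meaningful quantity, and it is what the curve-shape checks in this package
  use.
* The default gluteal layout of the synthetic generator places origin and
  insertion at near-equal distances from the joint center; in that regime
  the perpendicular foot never leaves the segment over the whole sweep, so
  the gluteal curves are identical under both conventions.

## The synthetic generator

Real inputs to this pipeline are CT-derived, segmented bone meshes. The
generator replaces them with stylized analytic solids — an ellipsoidal
pelvis, cylindrical femur/tibia/fibula shafts, a spherical femoral-head cap
sampled on a Fibonacci lattice — because the pipeline only ever consumes
surface points, attachment patches and head samples, and analytic solids
give *exact* oracles: attachment patches are point-symmetric disks whose
mean equals the nominal centroid exactly, and the true sphere center,
attachment centroids and (for planar layouts) the closed-form per-angle
moment arm are all known in closed form. Bone lattices are deterministic;
the seed governs only head-sample noise and placement jitter.

The default layout was designed once, before testing, to reproduce the
qualitative extensor behavior expected of small leaping primates:

* gluteal arms rise monotonically with hip extension (origins sit high on
  the iliac base close to the joint, insertions on a proximal trochanteric
  flange at a matching radius);
* hamstring arms follow a bell with an interior peak at 90°–110° (ischial
  origins, tibial insertions, the semitendinosus placeable toward the tibial
  mid-shaft via `st_insertion_frac`);
* hamstring strains stay in roughly the 77%–117% range across the sweep and
  every muscle is exactly at 100% at the reference pose.

Morphotype presets encode the torque-versus-velocity contrast as a single
radial scaling of all attachment positions about the hip center
(`trunk_leaper` ×1.15, `horizontal_leaper` ×0.88), which scales every arm
pointwise while leaving strains untouched. They are illustrative parameter
choices, not inferred anatomy. Default body masses span the 120–700 g range
typical of the marmoset/tamarin radiation.

**Known limitations.** The near-equal-radius gluteal layout that yields a
monotone infinite-line arm over the full 140° sweep necessarily implies a
large gluteal length excursion (roughly 34%–130% of resting length): a
monotonically growing arm *is* an accelerating length change, so arm
monotonicity and a narrow strain range cannot both hold for a straight
chord. Real gluteals, whose arms plateau, keep their strains in the optimal
band; the fixture trades that realism for an exactly monotone oracle
property. More generally the generator does not emulate realistic bone
shape, curved muscle paths, areal attachment weighting, or segmentation
noise — passing tests demonstrate the correctness of the geometry pipeline,
not anatomical fidelity of any particular species.

## Robustness analyses

Three perturbation studies accompany the pipeline, reported per muscle,
angle and quantity as mean/sd/min/max:

* **Placement repeatability** re-enacts repeated manual placement of
  attachment centroids: isotropic Gaussian jitter (σ = 0.5 mm by default)
  followed by re-projection to the nearest patch point, with the whole sweep
  recomputed per replicate. It is bit-reproducible given the seed, and σ = 0
  reproduces the baseline with zero dispersion. On the default fixture the
  within-placement dispersion is below, but within a factor of two of, the
  between-model spread of a four-model cohort — the 0.5 mm default is
  deliberately conservative for attachment radii of only 3–7 mm, where a
  manual placement protocol on real bone surfaces is expected to do better.
* **Mass perturbation** recomputes the sweep at mass·(1 + f) for
  f ∈ {−0.2, −0.1, +0.1, +0.2}. Raw arms and lengths are untouched;
  normalized values scale by exactly (1 + f)^−0.33, and the implementation
  reproduces that factor to ≤ 1e−12 relative error (the recomputation is a
  genuine re-run, the factor an analytic check).
* **Origin shift** moves the biceps femoris origin along the pelvis long
  axis (first principal component of the pelvis cloud, oriented away from
  the joint) by ±10% and ±20% of the effective pelvis length, snapping back
  to the nearest pelvis surface point. The synthetic pelvis carries a dense
  ischial ridge of surface points through the biceps femoris origin so the
  snap slides along an actual surface feature. Shifting the origin away from
  the joint lengthens the reference-pose arm monotonically across the four
  levels.

## Numerical choices and degenerate inputs

* Degenerate sphere fits (fewer than 4 points, coplanar or coincident
  configurations, non-positive fitted radius) raise errors rather than
  returning garbage; so do coincident line-of-action endpoints.
* "Effective" pelvis and femur lengths are maximum pairwise vertex distances
  (caliper lengths) — a reproducible convention where an axis-projected
  length would be ambiguous.
* Strain-band bounds are inclusive; ties in hamstring peak location are
  broken toward the smaller angle (`which.max`).
* All outputs are invariant to within 1e−9 under a global rigid transform of
  every input, and CSV outputs round-trip losslessly (17 significant digits)
  under a provenance header (package version, configuration hash, fitted
  sphere, seed) sufficient to re-run the producing command. Output files are
  byte-deterministic for equal inputs.
* Vertex indices are 0-based in JSON descriptors (converted on read; OBJ on
  disk is 1-based but is parsed as raw `v` records).

## Problem sizes

The shipped tests and the acceptance script use the generator's default
sizes: ~600-point pelvis ellipsoid plus shaft lattices (~2,600 points per
model), 200 femoral-head samples, 15-angle sweeps over 5 muscles (75 records
per model), cohorts of 4 models, 5 placement replicates, and 20 random
planar layouts for the oracle comparison. A full synth → sweep →
sensitivity → summarize chain over a 4-model cohort completes in seconds on
one core.

## A worked sweep

```{r example, eval = FALSE}
model <- generate_model(synthetic_spec(seed = 1, body_mass = 350))
curves <- hip_sweep(model)          # segment-clamped default
summary(curves)
plot(hip_sweep(model, clamp = FALSE))  # infinite-line arms: bell shapes visible

rep_place <- placement_repeatability(model, sigma_mm = 0.5, replicates = 5,
                                     seed = 1)
rep_mass <- mass_perturbation(model)
rep_shift <- origin_shift(model)
relative_lengths(model)
```
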