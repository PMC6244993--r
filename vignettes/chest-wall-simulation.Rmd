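---
title: "Simulating the chest wall: the model behind breastvol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the chest wall: the model behind breastvol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breastvol)
```

## The measurement problem

A 3-D surface scan shows only skin. To measure a breast volume the open skin
patch must be closed at the back by a surface standing in for the chest wall
— skin, pectoral muscle and rib cage without breast tissue. `breastvol`
implements a geometric simulation of that surface driven entirely by five
palpable landmarks, so that the whole measurement is reproducible from a mesh
and a landmark file with no interactive steps.

Units are fixed throughout: coordinates in mm, volumes in ml
(1 ml = 1000 mm³), areas in cm² (1 cm² = 100 mm²). Scanner exports in mm are
assumed; nothing else in the pipeline carries units.

## Pipeline and assumptions

1. **Reference frame.** The unit vector from the left to the right
   midaxillary landmark is the right axis; the component of (sternomanubrial
   − midpoint of the midaxillaries) orthogonal to it is the anterior axis;
   the superior axis completes a right-handed triple. This replaces the
   manual "place the scan in the frame" step of interactive tools with a
   deterministic construction; a manual 4×4 override can be passed as
   `frame`. The construction assumes the midaxillary stickers sit at
   comparable heights (they are placed at the middle of the armpit), so that
   the sternomanubrial offset from their midpoint is dominated by its
   anterior component. It degenerates — and errors — when the
   sternomanubrial point falls within 5° of the midaxillary axis.
2. **Boundary.** Three of the eight boundary points are anchored on
   landmarks (the sternomanubrial point shifted to the parasternal line, the
   superolateral landmark, the midaxillary landmark); five are placed by the
   `boundary_offsets()` recipe. The original method's "fixed relative
   distances" were never published, so the recipe is explicit, versioned
   configuration rather than code: all fractions are relative to the
   inter-midaxillary distance (about 280 mm on an adult torso), the one
   robust inter-landmark length. Defaults (parasternal 0.02, nipple drop
   0.18, inframammary drop 0.40, inferior x-fractions 0.70/0.45/0.15) were
   chosen once to reproduce the published boundary figure qualitatively and
   are deliberately not tuned per subject. A closed uniform Catmull–Rom
   spline interpolates the eight points — interpolation, not smoothing,
   because the points are the boundary definition; locality avoids the
   oscillation a global smoother shows with eight knots. Each of 512 dense
   samples is re-projected to the exact nearest point on the mesh, which is
   idempotent and continuous even at the lateral silhouette where an
   anterior-axis ray grazes.
3. **Bézier framework.** The boundary is split into upper and lower arcs at
   the exact medial and lateral x-extrema of the smooth spline (solved by
   local optimisation; an argmax over discrete samples tie-breaks unstably
   along the flat silhouette of a tessellated trunk and would break rigid
   equivariance). K vertical cubic Bézier curves join the arcs at matched
   normalized arc length. The upper handle direction is estimated from the
   mean of nearest-surface samples 5–10 mm superior to the upper end point,
   projected into the plane spanned by the chord and the anterior axis — the
   wall continues the slope of the visible chest. The lower handle is the
   chord-reflection of the upper one, making each curve symmetric about the
   chord's perpendicular bisector when the local surface is; the method
   specifies only the upper direction, and reflection avoids inventing an
   inferior surface probe. Both handle lengths equal BCHL × chord length
   (one handle length per curve). BCHL ∈ [0, 1], presets `bchl020`,
   `bchl033` (default), `bchl050`: longer handles give more convex walls.
4. **Loft and cut.** The K curves are evaluated at M + 1 parameters and
   triangulated (end columns collapse to the split points, like the poles of
   a sphere grid). The skin is resampled over the same parameter grid by
   anterior-axis projection (most anterior intersection = skin, not back;
   nearest-point fallback beyond the silhouette), so skin and wall share
   their boundary ring vertex-for-vertex and stitch into a watertight solid
   by construction — no general boolean CSG, which is fragile exactly where
   the two surfaces touch. Wall-through-skin intersections are counted
   (threshold 0.1 mm, the weld tolerance scale) and reported, never
   repaired: a wall poking through thin tissue near the boundary is
   information about the parameter choice, not a mesh defect.

## Resolution

K = M = 32 by default. On the synthetic subjects the enclosed volume moves by
under 0.5 % when both are doubled (the refinement check in the test suite);
24 × 24 leaves about 0.7 % on the table, which is why the default is one
notch finer. Validation-closure computations in the acceptance tests use
64 × 64, where the remaining quadrature error is a few tenths of a ml.

## Validation machinery

Distance maps sample one signed distance per simulated-wall face at the face
centroid (faces, not vertices, are what the original tool colours): the exact
nearest-point distance to the true wall, signed by the anterior component of
the offset. The volume error is wall area × mean signed distance / 10 (ml);
the mean is area-weighted by default because loft faces vary in size — an
unweighted variant (`weighted = FALSE`) mirrors tools that average per face.
Faces whose nearest point lands on an open edge of the truth patch are
flagged as outside coverage and excluded from means, with a warning.
Landmark repeatability uses point-to-point distances with axis restrictions:
midaxillary deviations count only the ventral–dorsal component (the lateral
boundary is insensitive to superior–inferior slips along the midaxillary
line), sternomanubrial only superior–inferior, superolateral the full 3-D
distance. The t-tests are the classical (non-Welch) paired and one-sample
forms. Identically equal paired samples return t = 0, p = 1; any other
zero-variance input errors, because the statistic is undefined and silently
returning anything would hide a degenerate design.

## What the synthetic subjects emulate — and what they do not

`generate_torso()` builds an elliptic-cylinder trunk (semi-axes 140 × 95 mm,
600 mm tall) whose anterior semi-axis is scaled by a parabolic profile in
height (`profile_drop`, default 18 mm at 150 mm from the apex). The profile
matters: on an exact cylinder the vertical surface rulings are straight, the
estimated handle directions coincide with the chords, and BCHL has no effect
at all — the parameter only acts on a chest that is convex in the vertical
direction, as real rib cages are. A parabolic section also has a useful
property: it is reproduced almost exactly by a symmetric cubic Bézier with
tangent handles of one third of the chord, which is consistent with the
published preference for BCHL = 0.33. `profile_drop = 0` recovers the flat
(ruled) case and is used in tests where straight chords are the exact truth.

The breast is a half-ellipsoid displacement bump (defaults a = 50, b = 40,
c = 55 mm, centred 62 mm lateral of the midline) faded by a C¹ smoothstep
ramp over the outer `blend` mm (default 8) of its elliptic footprint, so the
breast–trunk transition — where the superolateral landmark belongs — has a
defined location. Displacing along the anterior axis makes the added volume
exactly the integral of the height field: (2/3)πabc without blending, times
a blend factor computed by quadrature and reported
(`subject$blend_factor`). The sternomanubrial level sits `superior_margin`
(default 10) mm above the footprint top, matching the anatomy in which
breast tissue ends at the second rib: the boundary curve must enclose the
footprint, because tissue outside the drawn boundary is — as with any
boundary-based method — not counted. Landmark jitter is isotropic Gaussian,
seeded, applied after the anatomical placement.

These subjects exercise every pipeline stage against analytic truth, but
they are smooth, symmetric and scar-free: passing the recovery tests shows
the geometry engine is correct, not that the boundary recipe or a given BCHL
is clinically accurate for a particular patient. Ptotic breasts with a
folded inframammary crease, scarred or deformed chest walls, and
skin-texture noise from real scanners are outside what the generator
emulates.

## Numerical choices and degenerate inputs

* Degenerate faces (area < 1e−10 mm²) are dropped at load; watertightness
  means zero open edges and globally consistent winding, checked before any
  enclosed-volume computation, and an inward-oriented mesh yields |V| with a
  warning.
* OBJ parsing ignores normals, textures, materials and groups; polygons are
  fan-triangulated from the first vertex; negative (relative) indices are
  accepted.
* Boundary placement errors out when a landmark lies more than 60 mm off the
  mesh, when a boundary point must travel farther than that in the frontal
  plane, or when the eight points (or the fitted curve) self-intersect in
  frontal projection. Coincident consecutive boundary points are an error,
  not a silently collapsed knot.
* Bézier columns whose chord is shorter than 1e−6 mm degenerate to points
  (the grid poles). Columns out of medial-to-lateral order by more than
  0.01 mm in x trigger a self-intersection warning; the loft is reported,
  not untangled.
* All randomness (landmark jitter only) flows through one seed; the
  estimator itself is deterministic, and rigid motions of the inputs commute
  with the pipeline to floating-point precision because every computation
  happens in frame coordinates.

## Independent oracles

The test suite never checks the geometry against itself: enclosed volumes
are cross-checked by a column-parity voxel counter, Bézier evaluation
against de Casteljau subdivision, nearest-point queries against exhaustive
search over all triangles, cut volumes against analytic solids (boxes,
spheres, a plane-cut hemisphere, the half-ellipsoid bump), and the
volume-error statistic against the enclosed volume between two welded walls.
A small incremental convex hull exists solely to build random convex solids
with exactly computable volumes for those checks.

## Known limitations

* The boundary-offset defaults are this package's declared choice; the
  original tool's values are unpublished and may differ.
* The superolateral boundary depends on a soft-tissue transition that is
  genuinely ambiguous; its larger rater variability propagates into the
  boundary and hence the volume.
* High BCHL on small breasts can push the wall through the skin; the result
  is still computed (signed), with the protrusion count as the quality
  signal.
* Validation against a true chest wall requires a breastless side or an
  external truth surface; on bilateral-breast scans only plausibility
  checks (monotonicity in BCHL, symmetry) are available.
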