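---
title: "Osteological range of motion from vertebral meshes: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Osteological range of motion from vertebral meshes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteoROM)
```

## The problem and the model

Given watertight triangle meshes of a series of vertebrae, osteoROM estimates
how far each intervertebral joint can rotate before the bones either collide
or the zygapophyseal facets disarticulate. The pipeline is:

1. **Neutral pose (ONP).** Adjacent vertebrae are placed so that the facing
   pre- and postzygapophyseal facets overlap congruently; this articulated
   configuration is the zero pose of every joint.
2. **Centre of rotation (COR).** A sphere is fitted (algebraic least squares)
   to the postzygapophyseal facet outline of the anterior (cranial) vertebra
   of each joint; the sphere centre is the COR. Because any rotation about a
   point preserves distances to that point, facets lying on a sphere around
   the COR slide along their own articular surface under every rotation —
   which is exactly why the sphere fit is the right COR estimator for
   zygapophyseal joints.
3. **Exhaustive interacting sweep.** Each joint is actuated over the full
   grid of (roll, yaw, pitch) Euler triples (default step 2°), all other
   joints held at neutral. A pose is *viable* when (a) the two adjacent bone
   meshes do not intersect and (b) the moving anterior vertebra intersects
   both the left and the right articulation gap volume — prisms obtained by
   extruding the posterior vertebra's prezygapophyseal facets across the
   joint space. Criterion (b) encodes disarticulation at 0% facet overlap:
   the most permissive, purely osteological articulation bound.
4. **Summaries.** Viable pose sets are cosine-corrected, hulled with a
   Delaunay alpha shape (volume in cubed degrees), reduced to per-axis
   extrema, and summed over the chain.

Axes and signs: x is the series long-axis (roll), y dorso-ventral (yaw), z
latero-lateral (pitch); positive roll is clockwise seen from anterior,
positive yaw to the right, positive pitch dorsal.

### Rotation order and the cosine correction

Rotations compose intrinsically as roll about the joint x-axis, then yaw
about the rotated y-axis, then pitch about the rotated z-axis
(`R = Rx(roll) Ry(yaw) Rz(pitch)` in joint coordinates). At yaw = ±90° the
roll and pitch axes coincide, so equal roll steps near extreme yaw span less
orientation space than near neutral. The corrected coordinates
`(roll·cos(yaw), yaw, pitch)` remove this distortion; integrating the
correction over the full Euler box `roll, pitch ∈ [−180°, 180°]`,
`yaw ∈ [−90°, 90°]` gives `360·360·(360/π) ≈ 1.485×10⁷ deg³`, the total
volume of orientation space, which the test suite verifies to 0.5%.

### Alpha shapes and the critical alpha

ROM volumes use a Delaunay alpha complex: tetrahedra with circumradius ≤ α
are kept and their volumes summed. The preset α is 50; when the *critical*
alpha exceeds 50 the critical value is used instead. We define the critical
alpha as the smallest circumradius threshold at which every input point is a
vertex of a retained tetrahedron **and** the retained tetrahedra form one
face-connected solid. The connectivity clause matters for split viable sets:
two dense clusters 100° apart have a critical alpha above 50, so the
fallback engages and the reported shape encloses all points as one region.

Numerical choices: input points receive a deterministic jitter of 10⁻⁷ of
their extent so grid-like data are in general position for the incremental
(Bowyer–Watson) triangulation; tetrahedron volumes and circumradii are then
measured on the *original* coordinates. Degenerate slivers (zero original
volume, artefacts of the jitter on cospherical points) are assigned radius
zero: they carry no volume and, in the unjittered limit, are part of the
interface between their neighbours, so they participate in coverage and
connectivity from α = 0 without ever gating the filter.

### ONP refinement

The paper-level procedure placed vertebrae manually. `align_onp()` is a
derivative-free local refiner around a user-supplied initial placement. The
objective combines (i) silhouette overlap of the facing facet patches
projected on the sagittal, frontal and transverse planes, (ii) a tangential
facet-centroid alignment term, and (iii) a gap-uniformity term (variance of
point-to-facet distances). Term (iii) is what makes the optimum sharp: for
congruently seated facets the clearance is uniform across the facet, whereas
silhouette overlap alone is flat whenever the smaller facet's silhouette
sits inside the larger one, and a rotation about the COR can masquerade as a
translation. With these terms, poses perturbed by up to 5° / 0.5 mm are
recovered to better than 0.5° and 0.1 mm on the synthetic fixtures. The
weights (30 on centroid misalignment in mm², 200 on gap variance in mm²)
were chosen for nested, congruent facets; for badly eroded real facets the
gap-uniformity assumption weakens and the overlap floor (default 0.5) guards
against accepting a bad seat.

### Articulation gap volumes

The gap prisms extrude each prezygapophyseal facet along its mean normal by
the neutral facet gap plus a margin of one gap (prism length = 2 gaps by
default, configurable via `margin_factor`). The original workflow moved a
duplicated facet "up" until it filled the joint space, fixing the length
implicitly; ours is explicit. Growing the margin can only grow the
articulated set (a property the tests check).

## The synthetic vertebra generator

`make_vertebra()` builds stylised vertebrae as rigid assemblies of closed
components: a conical centrum (cranial face pivoted about its dorsal edge so
the ventral edge is angled caudally; tilt strictly removes ventral material),
a caudally leaning spinous process, a neural-arch roof, four zygapophyseal
plates, and dorsolateral ridge wedges on the prezygapophyses. Component
dimensions default to a mid-cervical vertebra of a small arboreal mammal
(centrum 12 mm × 8 mm; joint gaps 10% / 5% of centrum length, conventions in
lieu of unpublished specimen-specific radiographic ratios).

Both postzygapophyseal facets lie exactly on one sphere centred at the
intended joint COR, so `fit_sphere()` recovers the ground truth to numerical
precision and every rotation about the COR slides the facets along their
articular sphere. The prezygapophyseal facets are concentric patches one
facet-gap below. Chains built by `make_chain()` share the articular geometry
across each joint and are viable at the all-zero pose by construction.

What the generator emulates, and deliberately does not:

* It **does** reproduce the contact mechanisms that govern osteological ROM:
  facet arc length (pitch range to disarticulation), facet width (yaw),
  anterior facet tilt, ridge height (roll stop), centrum face tilt (ventral
  pitch clearance), spinous processes (dorsal pitch stop when tall), and
  bilateral mirror symmetry.
* It does **not** produce anatomically continuous bone. The components are
  disjoint closed solids with clearances; the space a real lamina or pedicle
  would occupy is partly empty. At extreme combined rotations a moving
  vertebra can thread through such gaps, producing isolated "viable" poses
  that real bone would forbid. The neural-arch roof closes the worst of
  these paths, but one remains: at strongly coupled roll–yaw postures the
  postzygapophysis can dip into the empty valley medial to the
  prezygapophyseal facets. For this reason the ridge-height mechanism is
  evaluated as *roll capacity near neutral yaw and pitch* (|yaw|, |pitch| ≤
  4°); the pitch mechanisms are evaluated on the full interacting grid. A
  green mechanism test therefore establishes the direction of the effect for
  the stated family and measurement band, not specimen-level magnitudes.

The mechanism families used by the acceptance tests (chosen before
measurement so that the intended contact is the binding constraint, mirroring
the anatomy each mechanism is attributed to):

* prezygapophysis length 2.5 / 4 / 5.5 mm with postzygapophysis 3 mm and
  centrum tilt 30° (so disarticulation, not centrum contact, bounds pitch);
* ridge height 1.0 / 1.6 / 2.6 mm at default parameters;
* centrum face tilt 0 / 12 / 25° with 6 / 5 mm facets (so centrum contact,
  not disarticulation, bounds ventral pitch).

## Tunable parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| grid step | 2 | deg | pose-space resolution; halving it refines, never removes, viable poses |
| grid bounds | ±90 roll/yaw, −90/+60 pitch | deg | search window; volumes are comparable only across identical bounds |
| alpha | 50 | deg | alpha-shape detail; critical-alpha fallback guarantees all points enclosed |
| margin_factor | 1 | facet gaps | articulation prism margin |
| body/zyg gap ratios | 0.10 / 0.05 | fraction of centrum length | neutral spacing conventions |
| decimate_target | off | faces | mesh budget before sweeping |

## Degenerate inputs and tie-breaks

* Fewer than 4 distinct (or coplanar) corrected poses: alpha volume 0 with a
  warning; extrema still reported from the raw angles.
* Empty viable set at a joint: zeros plus a warning in the chain summary.
* Maximum-turn composition breaks ties lexicographically (max yaw, then max
  roll, then max pitch) and reports — but does not forbid — whole-chain
  self-collisions between non-adjacent vertebrae, matching how per-joint
  maxima are composed into neck renderings.
* Meshes with small holes (< 100 boundary edges per loop) can be repaired by
  fan filling; larger defects are errors.

## Known limitations

* Pure rotations about a fixed COR; no translational degrees of freedom.
* Osteology only: no soft-tissue constraints, so ROM is an upper bound.
* The occipital and atlanto-axial joints are out of scope (their anatomy
  defeats the facet-based articulation criterion).
* The synthetic fixtures are mechanism-level stand-ins, not statistical
  shape models; conclusions transfer to real specimens only at the level of
  directions of effects.

## Reproducibility

All randomness flows from explicit seeds; two runs with equal configurations
produce byte-identical sweep CSVs and summaries. `run_pipeline()` writes a
manifest with the package version, the full configuration and its hash next
to every report bundle.
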