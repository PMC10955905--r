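---
title: "Geometric methods for automated fenestration planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric methods for automated fenestration planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fenplan)
```

## The planning problem

A physician-modified endograft (PMEG) is a commercial tube graft in which
the surgeon cuts fenestrations so that, once deployed, each hole faces the
ostium of a visceral artery.  Two constraints compete: every fenestration
must sit at its vessel's circumferential angle and axial depth, and no
fenestration may intersect the metal strut rings of the stent frame, which
a cautery tool cannot cross.  Because the graft may be rotated and
translated axially as a rigid body before modification, planning reduces to
a search over two continuous degrees of freedom plus, in hard cases, small
per-vessel concessions.

`fenplan` carries out this search in a developed (flattened) coordinate
system and maps the result back to 3D.  This vignette explains each stage,
its assumptions, and the numerical choices made where the design space was
genuinely open.

## Coordinates and conventions

All planning happens in the **(AL, PGD)** plane:

* **PGD** (proximal graft distance) increases distally from the proximal
  fabric edge; row 0 of every mask is the proximal edge.
* **AL** (arclength) is the circumferential distance around the deployed
  graft, `AL = phi/360 * pi * D`.  The angle `phi` is measured from a fixed
  **datum** direction (default: patient-anterior) projected into each
  cross-section plane, **clockwise when viewed from the proximal end** —
  the surgeon's en-face convention.  All mask arithmetic is half-open and
  0-based, pixel centres at `(index + 0.5) * resolution`.

A fixed, documented convention matters more than any particular choice:
the OR instructions are only reproducible if AL means the same thing on
the mask, on the mesh and on the printed sheet.  For the same reason the
mesh seam (below) is cut along the `phi = 0` datum generator, so the 2D
rectangle's AL origin coincides with the measurement datum.  We use the
projected-datum frame rather than parallel transport for ring placement:
rotation-minimizing frames accumulate holonomy along tortuous curves,
which would silently rotate the seam away from the datum; projecting a
fixed direction cannot, provided the tangent never becomes parallel to the
datum (true for any aorta-like, roughly axial tube).  Rotation-minimizing
(double-reflection) frames are still used for the per-station centerline
triads, where no external reference is needed and Frenet frames would flip
at inflection points.

Masks are built at the **deployed** diameter, not the nominal fabric
diameter, so that one millimetre of AL on the mask is one millimetre on
the implanted graft.  Whether AL should use deployed or nominal diameter
is a genuine modelling choice; we use deployed (the surface actually
cauterized) and flag it for clinical review.

## Stage 1 — graft and fenestration masks

A graft template is parametric: length, proximal/distal diameters, ring
positions, zigzag amplitude, wire width, peaks per ring.  Strut rings are
rasterized as symmetric triangular zigzags inflated by the wire half-width
plus a **safety margin** (default 1 mm, configurable) — cautery cannot
approach metal arbitrarily closely, and commercial strut patterns vary
enough that a conservative buffer is the honest representation.

* Uniform grafts unroll to a rectangle of width `pi * D`.  The column
  count is `round(pi * D / resolution)`; the *exact* circumference is
  stored separately and used for all AL conversions, so the rounding never
  accumulates.
* Tapered grafts develop isometrically onto an annular sector (a frustum's
  true development); struts are rasterized there and resampled onto a
  rectangular grid in which each PGD row's valid AL extent equals the
  local circumference, with out-of-circumference cells marked as
  unplaceable.  Zigzag legs are straight in (angle, axial) coordinates and
  curve so little under the sector map for clinical tapers (sagitta far
  below pixel size) that a few chords per leg rasterize them faithfully.

The default pixel size is **0.25 mm/px**: deviations are reported to
sub-millimetre precision, so the grid must resolve well below a
millimetre, while keeping a 100 mm x 30 mm graft mask around 400 x 327
pixels — small enough that a full search is instantaneous.

Fenestrations are measured from the segmented lumen: per-slice centroids
are smoothed into a centerline spline; each ostium projects to a foot
point (PGD = arclength from the graft top) and an angle `phi` about the
local tangent.  The fenestration mask renders each vessel as a filled disc
of its own diameter at `(AL mod period, PGD)`; the constellation is rigid
by construction.  Discs that would cross the fabric edge are rejected —
a hole at the edge would compromise the seal.

### Centerline smoothing

Cross-section centroids are computed on axial voxel slices (as segmented).
The smoothing spline default (`spar = 0.7` per coordinate against a
chord-length parameter) was chosen from a parameter-recovery study: an
under-smoothed centroid polyline is systematically *too long* — white
per-slice segmentation noise inflates arclength — which biases every PGD
measurement downstream by over a millimetre at 0.5 mm noise, while
`spar = 0.7` keeps the recovery error below 0.4 mm in every test condition
without flattening clinical-scale tortuosity (wavelengths of tens of mm).
GCV remains available (`spar = NULL`) and is the default in the generic
`fit_centerline_spline()`.

## Stage 2 — the alignment search

Sliding the fenestration mask over the graft mask with 1-pixel steps (the
finest grid the masks support) evaluates every rotational and axial
alignment.  The overlap count for all offsets at once is a 2D
cross-correlation — circular along AL, zero-padded along PGD — computed by
FFT and rounded back to exact integer counts; tests assert bit-exact
equality with a nested-loop brute force.  Offsets that would push any
fenestration past a fabric edge are excluded from the grid.

Among zero-overlap alignments the planner minimizes the summed per-vessel
deviation `delta = sqrt(dAL^2 + dPGD^2)` (AL difference on the shorter
arc), with deterministic tie-breaking: smallest `|dPGD|`, then `|dAL|`,
then lexicographic.  Determinism matters because the report must be
byte-identical across reruns.

### Posterior relaxation

When no rigid alignment exists, non-prioritized vessels (the renals) may
shift individually in their posterior AL direction by up to **3 mm**,
pixel-quantized; prioritized vessels (CA, SMA) never move.  "Posterior"
is resolved per vessel as *toward* `phi = 180` from its nominal angle,
and is configurable, since the clinical statement (posterior displacement
of a renal ostium is tolerable for cannulation) is directional in the
patient, not in mask coordinates.  The search minimizes the summed
deviation with relaxation included in each vessel's delta, preferring
smaller total relaxation on ties — and the rigid solution is always
preferred when one exists, even if a relaxed combination would score
lower: relaxation is a concession, not an optimization dimension.  Whether
per-vessel PGD relaxation should also be allowed is left out deliberately;
only the arclength direction is relaxed.

## Stage 3 — deployed graft mesh

The deployed diameter is the mean lumen diameter over the proximal landing
zone — the first 10% of graft length from the graft top — capped at the
fabric diameter.  The cap is an engineering judgment: fabric cannot exceed
its manufactured size, and below it the graft conforms to the wall
(interference fit).  For tapered grafts the distal diameter scales by the
template's taper ratio and diameters interpolate linearly between rings.

The mesh sweeps rings of `n_circ` vertices (default 96) along the
centerline spline at roughly 1 mm axial spacing, in the projected-datum
frame, with the seam column duplicated so the surface is an explicit
topological disk (Euler characteristic 1).  A warning is raised when the
local curvature radius drops below the graft radius — the loft
self-intersects there, and a mesh-based planner has nothing honest to say
about a graft kinked that tightly.

## Stage 4 — rectangle parameterization

The cut mesh is flattened by a discrete harmonic map: the cotangent-weight
Laplacian `L = D − W` with `w_ij = (cot a_ij + cot b_ij)/2` (boundary
edges use their single cotangent; the sign convention makes `L` positive
semi-definite with zero row sums), boundary vertices pinned to the
rectangle — proximal ring to the top edge, distal ring to the bottom, the
two seam copies to the sides, each spaced proportionally to 3D chord
length — and the interior solved per coordinate from the Dirichlet system
`L_II v_I = −L_IB v_B` with a sparse direct factorization.  Pinning plus a
single linear solve is the standard realization of a graph-embedding
formulation in which a border-indicator right-hand side by itself would
not produce a usable embedding.

Chord-proportional (not uniform) boundary spacing reduces distortion for
tapered grafts, where the two rings have different circumferences.
Negative cotangent weights from obtuse triangles are kept as-is: the loft
is near-structured, so obtuse triangles are rare, and on all fixture
meshes the map has zero flipped faces; a clamping flag exists for meshes
where a guaranteed convex-combination (Tutte) map is preferred.  Cotangent
weights are not cosmetic: on curved tubes the uniform-weight embedding
remains bijective but measurably distorts angles more (see the
quasi-conformal comparison in the test suite).

## Stage 5 — texture mapping and the deviation report

Any 2D point maps to 3D by locating its uv triangle (uniform-grid spatial
index; exhaustive scan as fallback), computing barycentric coordinates by
the closed-form inversion `lambda = T^{-1}(p − p3)`, and applying the same
weights to the triangle's 3D vertices.  Points in numerical gaps between
triangles snap within `1e-6`.  The per-vessel deviation `delta_f` is the
Euclidean distance in the developed plane between the fitted fenestration
centre and its ground-truth ostium position, with the AL difference taken
on the shorter arc — the printed formula is plain Euclidean, and the
wrapped variant differs only for near-antipodal pairs, where the shorter
arc is the physically meaningful distance on a closed surface.

## The synthetic-anatomy generator

Because clinical CT segmentations are not required for development, every
stage is exercised against parametric anatomies with full ground truth:

* centerlines: straight, circular arc (radius 300 mm), or two-axis
  sinusoidal "tortuous" wander (8 mm and 6 mm amplitudes, 110/140 mm
  wavelengths) over a 150 mm aorta;
* circular cross-sections in axial planes, diameter 26 mm tapering by
  1 mm, rasterized at 0.7 mm isotropic voxels (CT-angiography scale);
* optional white per-slice centre noise (0–0.5 mm) emulating segmentation
  roughness — the smooth curve remains the truth;
* four ostia at clinically plausible sites: CA anterior (`phi` 30°,
  PGD 22 mm), SMA anterior (0°, 37 mm), right renal lateral (105°, 40 mm),
  left renal lateral-posterior (255°, 42 mm), each jittered ±3° / ±1.2 mm
  per seed.  The base sites sit inside open strut cells of the bundled
  template at its deployed diameter — the synthetic analogue of a surgeon
  having chosen a graft that can actually fit the patient.

What this generator does **not** emulate: elliptical or diseased lumen
cross-sections, thrombus and calcification, vessel take-off angles,
aortic wall deformation by the device, or population-scale anatomical
variability.  Passing the recovery study therefore demonstrates that the
*geometry pipeline* is correct and stable under measurement noise — not
that clinical deviations would match; post-implant deviation depends on
mechanics this package deliberately does not model.

Adversarial constructions (`generate_adversarial()`) complete the picture:
a strut layout that blocks a renal at every rigid offset but clears 2 mm
posteriorly, a fully strutted graft with no fit at all, and an ostium
beyond graft coverage.

## Problem sizes and runtime

Default problem sizes were chosen so a complete evaluation runs comfortably
on a laptop: 0.25 mm masks (~400 x 327), meshes of ~10^4 vertices (one
sparse factorization each), and an acceptance study of 100 seeded cases
across the three profiles and three noise levels.  On one CPU the full
pipeline takes well under a second per case.

## Known limitations

* Strut geometry is an idealized symmetric zigzag; vendor-exact patterns
  (and their regulatory sizing charts) are out of scope, which is why the
  safety margin is conservative and configurable.
* The tapered development assumes a linear frustum; barrel-shaped deployed
  configurations are not modelled.
* The deployed-diameter rule (landing-zone mean capped at nominal) does
  not model graft oversizing mechanics; the interaction between
  interference fit and the 10% landing-zone mean is an open clinical
  question.
* `delta_f` is a planning-time geometric quantity referenced to the
  preoperative segmentation; implantation adds deformation and deployment
  error that no mask arithmetic can capture.
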