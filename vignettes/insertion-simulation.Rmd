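---
title: "Simulating and optimizing cochlear-implant electrode insertion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and optimizing cochlear-implant electrode insertion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cochsim)
```

## The model

Preformed ("self-curling") perimodiolar electrode arrays are held straight
by an internal stylet and inserted with the Advance Off-Stylet (AOS)
technique: the array is advanced into the cochlea while the stylet is held
stationary, so the released distal portion reverts to its manufactured
spiral shape and curls around the modiolus. `cochsim` models this process
as planar rigid-body kinematics:

* **Shape over extraction.** The central path of the array at stylet
  extraction `s` is built by curvature composition: the distal arc of
  released length `r(s) = s` carries the manufactured curvature profile, a
  logarithmic spiral `r(theta) = a * exp(b * theta)` whose radius grows
  linearly with arc length; the proximal remainder keeps the slightly bowed
  "banana" start configuration (a circular arc of configurable sagitta,
  default 1.5 mm over the 18 mm path). Integrating a single curvature
  function guarantees positional and tangential (C1) continuity at the
  release point and exact arc-length conservation, the two invariants of an
  inextensible body released from the tip. Release is modelled as immediate
  and complete.
* **Areal outline.** The path is offset by 0.15 mm on the modiolar face and
  by 0.65 mm tapering to 0.45 mm on the lateral face, so the modelled
  width falls from 0.8 mm at the base to 0.6 mm at the tip; a conical cap
  of two straight lines closes the tip. Offsets use per-vertex normals with
  miter joins; stations whose offset would loop (curvature radius below
  the offset) are trimmed and flagged.
* **Cochlea.** The lumen is represented by inner and outer wall polylines.
  Synthetic cochleae are two offset logarithmic spirals around a tapering
  centerline, sized by the greatest lateral dimension of the basal turn
  (Escudé's distance A) and classed small/medium/large (A = 8, 9, 10 mm).
  A triangulated surface mesh can be flattened instead: a cutting
  half-plane containing the modiolar axis rotates in 5-degree steps, the
  extreme inner/outer points per angle are collected, and the cloud is
  projected onto its orthogonal-distance-regression plane.
* **Placement and scoring.** A pose (dx, dy, dphi) rotates the outline
  about the cochleostomy and translates it (feed is -x). Each outline
  cross-section is intersected with the lumen band in the signed
  wall-offset coordinate; penetrated sub-intervals are integrated into
  areas with the normal-offset Jacobian `(1 - kappa * u)`, and wall
  crossings are root-refined against the exact signed offset. The features
  (tip overlap fraction, body penetration fraction, contact regions,
  restraint, far-outside) feed a deterministic grade cascade (below).

## The three strategies

* **autoAOS** - rigid automated insertion through a drill canal: feed
  coupled 1:1 to extraction (`dx = dx0 + s`, with `dx0 = 7.6` mm so the
  white marker, 7.6 mm behind the tip, starts at the cochleostomy);
  lateral offset and rotation frozen after initial positioning.
* **manAOS** - the manual technique: same coupling, but a per-step
  rotation is chosen greedily to minimize the step overlap cost, capped at
  5 degrees per step. The magnitude of the real surgeon's compensatory
  movement has never been measured; greedy minimization with a rate cap is
  the weakest assumption that produces smooth, locally-sensible
  compensation, and the zero-rotation choice is always among the
  candidates, so every step does at least as well as autoAOS.
* **optIns** - individualized optimization over all three pose parameters
  under the constraints: monotone feed, full insertion with complete
  stylet removal, and rate caps against abrupt changes (0.5 mm/step beyond
  the 1:1 coupling for dx, 0.2 mm/step for dy, 5 degrees/step for dphi;
  the caps quantify "no abrupt changes", for which no published numbers
  exist).

The optIns solver first selects the terminal placement - the pose that
nests the fully curled array in the lumen - then runs two greedy sweeps
(forward from the start configuration and backward from the terminal
anchor), keeps the better, and finishes with coordinate-descent smoothing
passes; the objective is non-increasing across iterations and the autoAOS
plan serves as a dominated baseline. A purely forward greedy sweep proved
myopic here: it idles at zero cost until first contact and is then
cornered by the rate caps, which is why the terminal anchor exists.

**Terminal depth.** Full insertion is nominally the feed at which the
basal marker ribs reach the cochleostomy (the profile's insertable
length). Because rigid kinematics cannot deform the array into the last
fraction of a millimetre, the solver may choose its terminal feed within a
2 mm under-insertion tolerance below that value - mirroring the surgical
practice of stopping at firm resistance, and consistent with the
observation that strict AOS coupling tends to insert too deeply. An
explicit `dx_final` in the configuration is honoured exactly.

**Step cost.** `area + 0.5 * depth^2` by default: the overlap area plus a
quadratic penalty on the deepest local penetration, which discourages the
deep point contacts that the grade cascade punishes. Weights are
configurable, including a contact-count term (default weight 0).

## The trauma-risk scale

In its clinical form the scale is a subjective expert rating in which a human
compensates for the missing deformation simulation. `cochsim` replaces it
with a deterministic first-match cascade over the scale's quantitative
anchors, evaluated from grade IV down:

| Grade | Rule |
|---|---|
| IV | outline far outside the contour (beyond a wall by more than its local width), or restraint with >= 3 contact regions |
| III | tip region fully outside the lumen, body penetrated by >= its whole cross section, or restraint (inner- and outer-wall penetration within 2 mm along the path) |
| II | tip overlap > half the tip size, body penetration > 0.25 of the cross section, or a penetrating tip oriented into the wall at < 45 degrees |
| I | any remaining contact |
| 0 | no contact |

"Size" of the tip is operationalized as its area and "cross section" as
the local outline width; the 45-degree incidence threshold and the 2 mm
restraint window are configurable because the clinical scale states no
numbers for them. The I-to-II boundary sits exactly at a quarter of the
cross section. Determinism buys reproducibility at a price: a human rater
would forgive small, localized intersections that elastic deformation
would absorb; the cascade does not, so mid-insertion steps grade
systematically harsher here than a human would rate them.

## Synthetic fixtures: what they emulate, and what not

No measured electrode shape tables or segmented cochleae are publicly
available, so the package synthesizes both.

* Four electrode profiles span the modelled range of curling behaviour:
  two pronounced specimens, one moderate, one flat, ordered by the tip
  deflection (measured as tip-tangent rotation away from the straight
  axis, because a positional metric is non-monotone for spiral shapes).
  All archetypes share the radial growth per arc of the lumen family
  (0.095 mm/mm), as preformed perimodiolar arrays are designed to nest in
  an average cochlea; they differ in tip curl radius (1.25 / 1.6 / 2.1
  mm). A variability seed adds about 2 percent specimen-to-specimen
  perturbation.
* Three cochleae with distance A of 8, 9 and 10 mm cover the reported
  human range. Lumen widths (2.5 mm tapering to 1.4 mm) follow the
  whole-bony-labyrinth regime of CT-based contour tracing -
  wider than the scala tympani alone, which is reachable through
  `width_scale`.
* Extraction steps default to 0.25 mm (the coarse end of the 0.1-0.25 mm
  measurement range) to keep simulation batches fast; profiles carry 73
  states over 18 mm.

What passing tests on these fixtures do **not** show: real arrays deform
on contact (no structural mechanics is modelled, intentionally), real
cochleae are not perfect log-spiral bands, curling is not perfectly
planar, and the guiding-tube straightening of a drill-canal insertion is
absent. The fixtures are constructed so that a low-overlap plan exists;
they demonstrate the machinery and the ordering of strategies, not
clinical performance.

## Numerical choices

* Heading integration uses 2880 substeps over the 18 mm path; states carry
  361 vertices, keeping arc-length drift below 1e-3 mm.
* Overlap integration uses 90 body stations plus 8 cap stations; areas
  agree with an independent Monte-Carlo point-in-polygon oracle to within
  1 percent on band fixtures.
* Spiral fitting initializes the centre from an algebraic circle fit,
  solves the log-linear radius regression for a fixed centre, then
  polishes all four parameters against true orthogonal distances (BFGS).
  Straight segments are chosen by increasing the count 0 to 3 and stopping
  when another segment fails to improve the orthogonal RMS by 10 percent
  (or the fit is already numerically converged below 1e-7 mm); collinear
  inputs short-circuit to a segment-only model.
* Greedy searches break ties toward the incumbent pose (and toward plain
  AOS coupling for the feed), so contact-free stretches follow the
  canonical technique instead of drifting.
* The penetration gate excludes the drilled-access region outside the
  cochleostomy plane (x > 0 below the basal wall level plus 1 mm): the
  shank outside the cochlea is not scored.

## Reduced problem sizes in tests

The oracle for the optimizer uses a 6-step reduced profile and an absolute
pose lattice (0.25 mm in dx, 0.2 mm in dy, 5 degrees in dphi) enumerated
exactly by dynamic programming; batch-level properties run on the packaged
fixture set (4 arrays x 3 cochleae x 3 strategies = 36 insertions) at the
0.25 mm step. These sizes were chosen as the smallest instances that still
exercise every constraint.

## Known limitations

* No deformation: contact does not bend the array, so deep-insertion
  overlap is over-estimated relative to reality; subjective expert
  ratings can partially compensate for this, the deterministic cascade does
  not.
* The 2D restriction is faithful to planar-curling arrays but ignores
  out-of-plane excursions of real anatomies.
* manAOS frees only the rotation; whether a real surgeon also adjusts the
  lateral offset is unknown.
* The depth-of-first-contact metric is computed (`depth_first_contact`)
  but deliberately not summarized: as a single-contact measure it ignores
  secondary contacts and restraint.
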