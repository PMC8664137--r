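---
title: "Modelling the C-arm beam and its skin footprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the C-arm beam and its skin footprint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(beamskin)
```

## The model

beamskin treats the cardiovascular angiography system as a rigid geometry:
a point X-ray source rotating on a sphere of radius 700 mm about the
isocenter, a square flat-panel detector (200 × 200 mm housing, 175 × 175 mm
field of view) opposite it, the examination tabletop 150 mm below the
isocenter with a 40-mm pad, and the patient entrance reference point (PERP)
150 mm from the isocenter toward the tube, so the source-to-PERP distance is
SPD = 550 mm. The patient is a triangle surface mesh in the table frame:
origin at the isocenter, +x patient left, +y anterior, +z cranial,
millimetres everywhere. The tube sits below the table, so for a supine
patient the beam enters through the back.

A gantry angulation is parametrized spherically: with primary angle
$\alpha$ (positive LAO) about the cranio-caudal axis and secondary angle
$\beta$ (positive cranial) as elevation, the unit beam direction is
$d = (\sin\alpha\cos\beta,\ \cos\alpha\cos\beta,\ \sin\beta)$ and the
source sits at $-700\,d$. No manufacturer publishes its CAD rotation order;
any parametrization that reproduces the clinical sign conventions (left
pannings positive for LAO views, cranial pannings positive for CRA views)
is admissible, and this one was validated against those sign patterns.

Per view the pipeline computes, in order:

1. **Panning.** The table translation $(LD, 0, CCD)$ that puts the heart
   center on the central axis, solved in closed form by intersecting the
   axis with the horizontal plane through the heart. Table height is fixed;
   a near-horizontal beam ($|d_y| \le 10^{-6}$) has no solution at fixed
   height and is reported as a per-view error.
2. **SID.** The detector backs off until the image receptor cover clears
   the body by `clearance_mm` (100 mm default):
   $SID = \text{cover gap} + \text{clearance} + D_\max$, where $D_\max$ is
   the largest axial depth of any surface point within the detector
   footprint. The footprint is the housing square projected along the axis
   (a Chebyshev test in detector coordinates). Restricting the scan to the
   footprint matters at steep angulations, where shoulders far outside the
   beam would otherwise inflate the SID; the rule is configurable
   (`footprint = "housing" | "fov" | "full"`). The clearance is measured
   axially, consistent with reproducing a ~976-mm SID from a 593-mm SSD and
   a 233-mm chest.
3. **SSD.** First intersection of the central ray with the mesh
   (Möller–Trumbore in compiled code, with a 2-D angular-grid acceleration
   structure over the shared ray origin).
4. **A~p~.** The collimator tracks the FOV at a reference plane
   `fov_ref_offset_mm` beyond the SID, so by similar triangles
   $A_p = \left(\mathrm{fov} \cdot SSD / (SID + c)\right)^2$.
5. **A~s~.** The surface Boolean intersection between the beam pyramid and
   the entrance-visible skin (below).
6. **Overlaps.** Pairwise shared A~s~ area across the protocol's views.

## The FOV reference-plane offset

With the naive model $c = 0$ (FOV defined exactly at the SID), the
published per-view tables for the two reference anthropomorphic phantoms
are internally inconsistent: the printed (SID, SSD, A~p~) triplets imply a
field slightly smaller than $\mathrm{fov}\cdot SSD/SID$. A least-squares
fit of $c$ over the 20 printed triplets,

```{r}
male <- reference_geometry("male")
female <- reference_geometry("female")
fit_fov_offset(c(male$sid_mm, female$sid_mm),
               c(male$ssd_mm, female$ssd_mm),
               c(male$ap_mm2, female$ap_mm2))
```

recovers ≈ 26 mm, so the default is `fov_ref_offset_mm = 25`: the
FOV-defining plane sits about one inch beyond the nominal SID (a plausible
cover-to-detector internal spacing). Setting the offset to 0 restores the
naive model; the parameter exists precisely to expose this discrepancy
rather than hide it.

## The on-skin field A~s~

The beam is a square pyramid: apex at the source, four lateral planes
through the FOV square at the reference plane. The in-plane `u` axis is the
projection of the patient z axis, so detector rows stay aligned with the
table; `v = d × u`. A~s~ is computed on a refined copy of the mesh
(longest-edge bisection to a target edge, 2.5 mm by default; adaptive
bisection conserves area exactly and tolerates the long thin triangles of
prism-like fixtures, at the price of harmless T-junctions):

- a face wholly inside the four half-spaces belongs to the patch with
  weight 1;
- a face straddling the field rim is clipped exactly against the pyramid
  planes (Sutherland–Hodgman) and enters with its inside-area fraction as
  weight — an earlier centroid-membership rule showed a first-order rim
  bias (about −1% on a flat slab at 4-mm refinement) whenever the
  triangulation aligned with the field edges, which the exact clip removes;
- a face is kept only if the ray from the apex through its centroid hits
  that face first (visibility). This restricts the patch to the entrance
  surface: the beam-exit skin on the far side of the body is occluded by
  the body itself and excluded, matching what a CAD Boolean intersection
  against the entrance skin reports. Grazing hits are resolved to the
  nearest intersection beyond a 10^-6^-mm guard.

$A_s = \sum_f w_f\,a_f$ over member faces. Overlap between two views'
patches is the sum over shared member faces of the face area times the
smaller of its two weights; this makes the matrix symmetric and enforces
$\mathrm{overlap}(i,j) \le \min(A_{s,i}, A_{s,j})$ by construction, which
pairwise mesh Booleans would not guarantee numerically. All patches of a
study reference one shared refined mesh (faces indexed identically across
views), so membership comparisons are exact.

An independent Monte-Carlo oracle (`as_oracle_mc()`) estimates A~s~ by
stratified jittered rays over the FOV square: each hit contributes its
flat-plane area element mapped to the skin,
$\Delta a \cdot \cos\varphi \cdot (t/r_{\mathrm{ref}})^2 / \cos\theta_{inc}$.
On a flat perpendicular entrance this reduces algebraically to A~p~ exactly,
which the tests exploit. The oracle shares the ray-casting kernel but not
the classification path; clipping and oracle agree within 3 standard errors
on the torso across all ten protocol views.

## The synthetic phantom

No patient or phantom surface meshes are distributable with the package, so
`make_torso()` generates an analytic stand-in for a supine adult torso: a
superelliptic cylinder (exponent 2.5 — flatter back, convex chest), rounded
cranio-caudal caps, and a smooth cranial shoulder taper (15% width
reduction), resting dorsal-side-down on the pad plane at y = −110 mm. The
heart is a point at the configured left offset and at one third of the
chest depth from the frontal skin surface, halfway along the torso. The
male preset uses a 340 × 233 mm chest with a 30-mm heart offset; the female
preset 320 × 198 mm with a 20-mm offset, both with the one-third depth rule
(30/77 and 20/66 mm placements respectively). The 233-mm and 198-mm chest
depths are derived, not measured: they are the anterior–posterior extents
implied by the reference phantoms' printed PA-view SID and SSD under the
clearance rule. Generation is purely analytic and deterministic — the seed
only drives an optional surface-noise perturbation that is off by default —
so identical parameters give byte-identical STL output.

What the phantom does *not* emulate: arms, breasts, internal anatomy,
posture deformation on the pad, and the 1-mm-wall hollow-shell structure of
scanned phantom meshes (the engine consumes only the outer skin;
`extract_outer_surface()` reduces hollow shells by keeping the
largest-bounding-box component). Consequently, passing tests show that the
geometry engine is correct and that its outputs move the way the reference
study's do (SID up, SSD and A~p~ down with total panning; A~s~/A~p~ between
1.0 and 1.5; overlaps concentrated among neighbouring views) — they do not
certify agreement with any individual patient's anatomy.

## Numerical choices

- Degrees at every interface, radians internally; hardware-plausible ranges
  (|primary| ≤ 120°, |secondary| ≤ 60°) enforced at construction.
- Lengths carry full precision internally; the report layer rounds lengths
  to whole mm, areas to whole mm², ratios to 2 decimals.
- STL carries no units; millimetres are asserted by contract and checked by
  a bounding-box heuristic (diagonal outside 100–3000 mm warns). Vertices
  are merged within 10^-6^ mm on read; zero-area facets dropped.
- The depth scan in `solve_sid()` samples mesh vertices, so coarse meshes
  are internally densified to a 25-mm edge first.
- Non-watertight meshes are accepted by the ray and clipping paths (the
  validator's strict mode can demand watertightness).
- Pearson correlations use the Fisher z-transform interval with
  SE $1/\sqrt{n-3}$ (via `stats::cor.test`), which reproduces the reference
  study's printed confidence intervals to ±0.002. Overlap summary
  statistics run over all $n(n-1)/2$ unordered pairs *including* zeros;
  the reference tables' published means are only reproducible under that
  convention.
- The focal spot (1.2 mm) is recorded in the configuration but the source
  is a point: penumbra at these distances is below 0.2 mm, far below the
  refinement resolution.
- Backscatter `B` and table attenuation `k_ta` are user inputs with
  plausibility warnings (B in [1, 1.6], k_ta in [0.5, 1]); no lookup tables
  are shipped. The kerma-area-product correction assumes the meter's
  calibration plane is consistent with the entrance-plane A~p~ — a
  documented caveat, not a checked condition.

## Problem sizes

The examples and tests run the full protocol on the male torso preset at a
6-mm generation resolution refined to 3 mm (about 190k faces), which keeps
a complete 10-view study with overlap matrix under half a minute on one
core; the Monte-Carlo cross-checks use 10^4^ stratified rays per view.
Finer settings (5 mm / 2.5 mm, the defaults) change A~s~ by well under 2%,
per the convergence tests.

## Known limitations

- Panning is a pure x/z translation at fixed table height; table tilt and
  longitudinal float limits are not modelled.
- Collision handling is limited to the clearance rule; gantry/table corner
  collisions are out of scope.
- Collimation is fixed at the full FOV; per-view user collimation can be
  expressed by shrinking `fov_side_mm`.
- Dose magnitudes on the patch (beyond the two K~a,e~ corrections), wedge
  filters, scatter, and angulation-dependent table attenuation are out of
  scope.
```{r session}
sessionInfo()
```
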