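---
title: "Methods: 3D transmural scar assessment from LGE-CMR segmentations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D transmural scar assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(scartrans)
```

## The problem

Late gadolinium-enhanced cardiac MR (LGE-CMR) shows infarct scar as
hyperintense tissue inside the left-ventricular myocardium. Clinically
common 2D acquisitions have thick slices (about 1.5 x 1.5 x 8 mm), while
isotropic 3D acquisitions (about 1.5 mm acquired, 0.7-0.75 mm
reconstructed) are slow and rarely practical. `scartrans` implements a 3D
workflow that makes thick-slice data usable for volumetric substrate
analysis: thick-slice segmentations are upsampled to isotropic resolution
by shape-based interpolation, scar is segmented by a
full-width-half-maximum (FWHM) intensity criterion, and scar burden is
expressed *transmurally* - per epicardial surface point, as the fraction
of the wall thickness occupied by scar along an
endocardium-to-epicardium correspondence.

Inputs are a scalar image volume and a co-registered label volume with
codes 0 background, 1 blood pool, 2 myocardium, 3 scar (scar is part of
the wall; the geometric wall is labels 2 and 3). Volumes are read and
written as NIfTI-1; array axis 3 is the through-plane (long-axis)
direction and inputs are assumed short-axis aligned. Voxel centers sit at
`origin + index * spacing`, everything in millimetres.

## The wall-depth model

The core quantity is a harmonic wall coordinate: the Laplace problem

\[ \nabla^2 s = 0 \quad \text{in the wall}, \qquad
   s = 0 \text{ on the endocardium}, \quad
   s = 1 \text{ on the epicardium}, \]

with zero flux across the basal cut plane. Level sets of `s` define wall
layers; integral curves of its gradient define one-to-one
endocardium-epicardium correspondences that never cross. Per epicardial
mesh vertex, the correspondence is traced by integrating the normalized
negative gradient (first-order fixed step, `0.25 * min(spacing)` mm,
trilinear interpolation). Wall thickness is the arc length of the trace;
scar thickness is the summed length of scar-labelled steps (nearest-voxel
label at each step midpoint); transmurality `TsM` is their ratio, clamped
to [0, 1].

Derived quantities follow the same transmural logic:

* **Scar areas at transmurality thresholds.** For each threshold `tau`,
  the summed area of epicardial triangles whose vertices
  majority-satisfy "scar present (`TsM > 0`) and `TsM < tau`". The
  scar-present condition is a deliberate design choice: a vertex with no
  scar anywhere along its correspondence has `TsM = 0`, and counting it
  as "scar area below threshold" would be incoherent. The condition can
  be disabled (`require_scar = FALSE`).
* **Wall-depth layer partition.** Each scar voxel is binned by its `s`
  value with boundaries at 0.33, 0.67 and 0.97 of the wall depth:
  endocardial, midwall, epicardial layers plus an explicit
  subepicardial rim `[0.97, 1]`. The rim is kept as a fourth bin rather
  than merged into the epicardial layer so that the outermost 3% of the
  wall remains visible in the accounting; bin volumes sum exactly to the
  total scar volume.

## Scar segmentation (FWHM)

Scar is detected inside the wall mask by thresholding raw voxel
intensities at fixed fractions of a reference maximum: 0.45 for scar and
0.67 for the dense core (intensities between the two cutoffs are
heterogeneous, border-zone scar). The reference maximum itself is
computed after through-plane slab averaging over an ~8 mm window
(`slab_mm = 8`, or an explicit voxel count such as 12 neighbours at
0.75 mm reconstruction), so that high-resolution isotropic volumes are
not penalized by single-voxel noise relative to thick-slice 2D data. Two
further choices are fixed and logged:

* the maximum is taken over the *entire* wall mask after slab averaging,
  not over an operator-drawn region of interest, which keeps the
  operation deterministic (users can restrict the wall mask themselves);
* whether the reference maximum should be per-slice or global is not
  externally constrained; it is global here.
* edge slabs use truncated windows (the mean over available voxels), not
  zero padding, to avoid deflating the threshold near apex and base.

Thresholding scales with the maximum, so the segmentation is invariant
under global intensity rescaling.

## Resampling

**Downsampling** (2D-acquisition emulation) partitions the through-plane
extent into slabs of the target thickness. Image slabs average; label
slabs vote by occupancy - background, blood and wall (myocardium + scar
together) compete, the largest fraction wins with ties resolved
wall > blood > background, and a winning wall voxel becomes scar when the
scar fraction *relative to the wall occupancy* reaches 0.5. Measuring the
scar fraction within the wall, not within the whole slab, keeps thin-wall
slabs from being biased toward healthy myocardium.

**Upsampling** is shape-based interpolation: per-slice in-plane signed
distance maps (mm) of each structure's binary mask, interpolated linearly
along the through-plane axis, with the voxel assigned to the most
interior (most negative) distance and background where all are
non-negative. Scar-in-wall nesting is enforced hierarchically (wall
first, scar within wall). Empty and full slices take a constant +/- cap
so that structures appearing or vanishing between slices interpolate
sensibly. The output grid covers the full physical slab extent
(interpolation clamps beyond the outermost slice centers), and only the
through-plane axis is ever resampled. The particular published
"topologic" interpolation algorithm this emulates is not specified at
the level of detail needed to reproduce it exactly; signed-distance
shape-based interpolation was chosen because it is deterministic,
topology-friendly for convex-ish anatomy, and verifiable against phantom
ground truth (equivalence is asserted at the level of phantom-recovery
metrics, not algorithm identity).

**Slice-shift correction** translates each slice in-plane by an integer
number of voxels, either onto the section centroid of a reference
epicardial mesh or, lacking one, by wall-centroid continuity between
successive slices (pure gauge freedom - a common shift of all slices is
then unobservable and left uncorrected).

## Numerical design of the Laplace solver

A rasterized segmentation locates a smooth interface only to within half
a voxel, and on axis-aligned stretches the voxel faces sit systematically
off the true surface. Imposing `s = 0/1` at boundary voxel *centers*
turns out to be too crude for sub-percent fidelity to the analytic
annulus solution, so the solver reconstructs the interfaces at sub-voxel
precision first:

1. **Interface reconstruction.** For each interface (wall|blood,
   wall|background), the midpoints of all label-change faces form a point
   cloud. At every boundary voxel a quadric patch is fitted to the cloud
   by moving least squares in a local frame aligned with the
   signed-distance gradient. The transverse Gaussian window
   (`sigma_t = 8 * spacing`) is wide enough to span several staircase
   runs of the rasterization - runs have half-length about
   `sqrt(2 * R * h)` for curvature radius R - which is what makes the
   sub-voxel position identifiable at all; the normal window is
   `sigma_n = 2.5 * spacing`.
2. **Discretization.** Anisotropic 7-point finite differences with
   Shortley-Weller boundary arms: the Dirichlet value attaches where the
   reconstructed interface crosses the arm (fractional arm length
   `theta`, clamped to [0.05, 1], falling back to the voxel face at 0.5
   when a fit is unavailable). Missing neighbours (grid edge, basal cut)
   are mirrored (zero flux). All wall voxels are unknowns.
3. **Solve.** Jacobi-preconditioned BiCGSTAB to a relative residual of
   1e-5 (default), deterministic, with a direct sparse fallback on
   numerical breakdown; non-convergence within the iteration cap is an
   error that reports the final residual.

Two consequences are worth spelling out. First, endocardial boundary
voxels carry small positive solved values (about 0.03 on the reference
annulus) instead of exact zeros: the zero level lies on the reconstructed
endocardial surface, between the boundary voxel center and the blood.
Second, in a degenerate wall where every voxel touches a boundary (e.g. a
one-voxel wall), voxels take interface-implied intermediate values
(about 0.5 when touching both sides) rather than a pinned 0 or 1. Both
are deliberate: on the reference annulus (endocardial radius 20 mm,
epicardial 30 mm, 0.75 mm voxels) center-pinned Dirichlet values leave a
maximum interior error of about 0.05 against the analytic
`ln(r/20)/ln(30/20)`, face-centered conditions about 0.023, while the
reconstructed-interface scheme reaches below 0.01.

The same interface reconstruction drives surface extraction: marching
cubes runs on a signed distance field whose near-boundary band is
replaced by the fitted interface offsets, so mesh vertices land on the
underlying smooth surface rather than the voxel staircase (digital
sphere areas are recovered to about 2% at 1 mm voxels and well under 1%
at 0.5 mm).

Boundary classification itself is by face adjacency: wall voxels touching
blood are endocardial, touching background epicardial, with precedence
endo > epi for voxels touching both (keeps the `s = 0` surface connected
in thin walls; occurrences are reported). The basal cut is the topmost
occupied through-plane slice; its otherwise unclassified wall voxels get
zero-flux treatment. How the ventricular base should be treated is not
externally prescribed anywhere; zero flux is the least-committal choice
and matches the intuition that correspondences should not terminate on
the cut.

## Streamline tracing details

* Step size `0.25 * min(spacing)` mm; first-order (Euler) steps are
  adequate because the field is smooth and the step is a quarter voxel.
* The potential is extended with 0 in the blood pool and 1 in the
  background so gradients are defined right up to the surfaces.
* A trace ends when (a) the interpolated sub-voxel signed distance to
  the endocardial surface crosses zero - the landing point is backed up
  to the crossing - or (b) the potential drops below `eps_endo = 0.02`,
  in which case the remaining distance `s/|grad s|` is extrapolated and
  added. Both endpoints estimate the same surface; (b) covers regions
  where the discrete field is locally biased upward at jagged
  rasterization corners.
* Step midpoints are labelled by nearest voxel. Since every step lies in
  the wall by construction, a midpoint that rounds into blood or
  background falls back on the inner endpoint's label and then on the
  last in-wall label of the trace - otherwise full-thickness scar would
  be systematically under-measured by up to half a voxel per trace.
* Traces longer than 10x the maximal inscribed wall thickness, or
  meeting a vanishing gradient (< 1e-4 per mm), are flagged invalid,
  excluded from maps and counted in the QC report.

## The phantom generator

The test bed is analytic, not imaging data:

* **Annulus** (default endocardial radius 20 mm, wall 10 mm, height
  30 mm): a straight cylindrical wall whose exact potential is
  `ln(r/a)/ln(b/a)` and whose streamlines are radial, so prescribed
  transmural extents are *exact* oracles. The grid ends exactly at the
  top and bottom of the cylinder, making both ends zero-flux planes.
* **Truncated ellipsoid** (default endocardial semi-axes 20, 20, 32 mm,
  wall 8 mm, basal cut at 0.25 of the epicardial long semi-axis): the
  realism check with through-plane curvature and an apex. Ground-truth
  transmurality is defined along radial rays through the wall (an
  analytic proxy for the Laplace streamlines) and is therefore held to
  looser tolerances than the annulus.

Scar occupies an angular sector (default `[0, pi/2)`) out to a prescribed
transmural extent `f` measured from the endocardium. Intensities are
two-level with additive Gaussian noise: background 0.05, blood 0.6,
nulled myocardium 0.2, enhanced scar 1.0 (arbitrary units), `sd = 0.02`,
all overridable; the defaults put the 0.45 FWHM cutoff cleanly between
healthy and scar so segmentation errors reflect noise, not model overlap.
Labels are seed-independent; only the noise consumes the seed.

The rasterization grid places the symmetry axis on a voxel corner (the
grid is reflection-symmetric about the axis). This is the natural
cell-centered convention and avoids the degenerate alignment where
analytic surfaces pass exactly through voxel centers - the worst case for
any sub-voxel interface estimate, since a rasterized flat leaves a full
half-voxel ambiguity band.

What the phantoms deliberately do not emulate: MR physics (bias fields,
motion, partial k-space), papillary muscles, trabeculation, right
ventricle, non-convex scar shapes, through-plane slice profiles. Passing
the phantom suite shows the geometry/numerics chain is correct at
clinical voxel sizes; it does not validate segmentation of real LGE
contrast.

## Problem sizes and tolerances used by the test suite

Unit tests run on compact phantoms (annulus r 10/16 mm at 0.75 mm,
ellipsoid 12/18 mm at 1 mm); the acceptance suite and
`scripts/acceptance.R` use the full study geometry (annulus r 20/30 mm
and ellipsoid 20/28 mm at 0.75 mm, about 100k-120k wall voxels, solving
in a few seconds and tracing ~13k-21k vertices). Key tolerances: maximum
interior deviation from the analytic annulus potential 0.02; streamline
wall thickness 10 +/- 0.5 mm at every valid vertex (slab thickness exact
to one integration step); mean sector transmurality within 0.05 of the
prescribed extent; FWHM phantom scar Dice 0.95; thick-slice round-trip
wall Dice 0.90 at 8 mm with ICC(2,1) of matched-vertex transmurality
0.90; statistics match brute-force/ANOVA oracles to 1e-10.

## Statistics

`icc_2_1()` implements the two-way random effects, absolute agreement,
single-measurement intraclass correlation from the ANOVA mean squares;
`pearson_r()` the product-moment correlation with the two-sided t-test;
`mann_whitney_u()` the rank-sum U with exact enumeration for
`n1 + n2 <= 12` without ties and a tie- and continuity-corrected normal
approximation otherwise (all two-sided, matching the p < 0.05
convention). `map_concordance()` compares two transmurality maps by
nearest-vertex matching of valid vertices - the matching rule between
two meshes of the same anatomy is not externally specified; nearest
vertex after the maps' shared physical frame is the simplest
deterministic choice and is reported with the matched count.

## Known limitations

* The Laplace solve and tracing assume a single 6-connected wall
  component with both boundary types; disconnected islands are an error,
  not silently dropped.
* Sub-voxel interface reconstruction assumes locally smooth anatomy; at
  genuinely sharp features (surgical clips, extreme trabeculation) it
  degrades toward face-centered placement.
* Thickness is measured along streamlines, which on strongly curved
  walls differs from ray-based or nearest-point definitions by design.
* The pipeline carries label-derived scar through resampling when the
  image grid no longer matches the segmentation grid (post-upsampling);
  FWHM re-detection happens only on matching grids.
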