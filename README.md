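# scartrans

Three-dimensional transmural assessment of myocardial infarct scar from
late gadolinium-enhanced cardiac MR (LGE-CMR) segmentations.

## What it does, and for whom

Clinical LGE-CMR is usually acquired as thick 2D slices
(~1.5 × 1.5 × 8 mm), while volumetric substrate analysis wants isotropic
3D data (~0.7–0.75 mm). `scartrans` is for imaging researchers and
electrophysiology groups who need volumetric scar characterization from
either kind of acquisition:

* **Shape-based upsampling** of anisotropic thick-slice label volumes to
  isotropic resolution (per-slice signed-distance interpolation with
  scar-in-wall nesting), plus thick-slice emulation and in-plane slice
  shift correction for validation studies.
* **FWHM scar segmentation** inside the myocardial wall: scar at 0.45 of
  the slab-averaged maximum signal intensity, dense core at 0.67
  (between the two = heterogeneous, border-zone scar), with scar/wall
  volume accounting in cm³.
* **Transmurality mapping** — the core method. A Laplace (harmonic) wall
  coordinate s with s = 0 at the endocardium and s = 1 at the
  epicardium is solved over the wall; streamlines of its gradient give
  point-wise endocardium–epicardium correspondences; per epicardial
  vertex, transmurality TsM = (scar length) / (wall thickness) along the
  correspondence. Derived outputs: scar areas at transmurality
  thresholds (0.1, 0.2, …) and scar volume by wall-depth layer
  (boundaries at 0.33, 0.67, 0.97 of the depth).
* **Concordance statistics** used to validate such reconstructions:
  Dice, symmetric surface (Hausdorff) distance, ICC(2,1), Pearson r,
  Mann–Whitney U, threshold-sweep correlation profiles, and
  nearest-vertex map concordance.
* **A synthetic left-ventricle phantom generator** (annulus and truncated
  ellipsoid) with analytic ground truth, so every stage is testable
  without patient data.

Label convention: 0 background, 1 blood pool, 2 myocardium, 3 scar
(scar ⊂ wall). I/O: NIfTI-1 volumes, ASCII PLY meshes with a per-vertex
`tsm` property, CSV/JSON tables.

## Worked example

A cylindrical-annulus phantom (endocardial radius 20 mm, wall 10 mm) with
a 90° scar sector of transmural extent 0.5:

```r
library(scartrans)

ph <- make_phantom(phantom_spec("annulus", transmural_extent = 0.5,
                                noise_sd = 0.02, seed = 7))
ph$labels
#> <label_volume> 88 x 88 x 40 voxels, spacing 0.75 x 0.75 x 0.75 mm, ...
#>   labels: background=108800, blood=89760, myocardium=98840, scar=12360

# emulate a 2D acquisition and upsample back to isotropic
seg2d <- slice_stack(ph$labels, 8)
seg3d <- upsample_topologic(seg2d, 0.75)

field <- solve_laplace(ph$labels)
#> <potential_field> 111200 wall voxels; residual 3.85e-06 after 39 iterations

epi <- extract_surface(ph$labels, "epi")
#> <surface_mesh> 12800 vertices, 24960 triangles, area 55.12 cm^2

map <- transmurality_map(trace_correspondences(field, epi, ph$labels))
scar_area_at_thresholds(map, epi)
#>   threshold  area_cm2
#> 1       0.1  0.000000
#> ...
#> 5       0.5  7.694125
#> 6       0.6 13.779811

layer_partition(ph$labels, field)
#>         layer from   to volume_cm3  fraction
#> 1 endocardial 0.00 0.33   2.885625 0.5533981
#> 2     midwall 0.33 0.67   2.328750 0.4466019
#> 3  epicardial 0.67 0.97   0.000000 0.0000000
#> 4         rim 0.97 1.00   0.000000 0.0000000
```

Reading the numbers: the scar sector was prescribed at half transmural
extent, so no epicardial vertex reaches TsM ≥ 0.6 — the threshold sweep
saturates at the full sector area (13.8 cm², one quarter of the 55.1 cm²
epicardium) and is zero below the prescribed extent; a 0.5-extent scar
starting at the endocardium lies entirely below s ≈ 0.55, splitting
between the endocardial and midwall layers. Mean TsM over the sector
vertices recovers 0.50 within ±0.01.

The same stages are scriptable from a shell via the thin CLI in
`inst/cli/scartrans` (`phantom`, `downsample`, `upsample`, `segment`,
`map`, `quantify`, `validate`, `run`), e.g.

```sh
Rscript inst/cli/scartrans run --config config.json -o out/
```

## Documentation

The methods vignette (`vignettes/transmural-scar-assessment.Rmd`)
describes the model and its assumptions, the numerical design (sub-voxel
interface reconstruction, Shortley–Weller discretization, streamline
termination rules), every tunable parameter with units and defaults, what
the phantoms do and do not emulate, and known limitations.
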