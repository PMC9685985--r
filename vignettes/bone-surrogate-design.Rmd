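---
title: "Designing mechanically calibrated 3D-printable femoral bone surrogates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing mechanically calibrated 3D-printable femoral bone surrogates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bonesurro)
```

## The problem

Biomechanical testing of implants, screws and fracture fixation needs femoral
bones with realistic stiffness and strength. Donor bones are scarce and
variable; commercial foam surrogates are either mechanically unrealistic or
expensive, and always generic in geometry. Fused-deposition-modelling (FDM)
printing can produce patient-specific femur replicas cheaply -- if the infill
that stands in for the trabecular bone is *mechanically calibrated* rather
than chosen by eye.

`bonesurro` implements that calibration workflow end to end:

1. **Volume I/O and calibration** -- read a CT volume (DICOM series, TIFF
   stack or MetaImage), map its grey values linearly onto a 0--1064
   bone-fraction scale (0 = air, 1064 = 100% bone), and downsample to a
   tractable working resolution.
2. **Segmentation** -- global threshold plus largest-component cleanup
   removes embedding and holder; morphological peeling separates the
   cortical shell from the interior; smoothing, an overlay hook for manual
   corrections, and cavity filling produce cortex and spongiosa masks;
   watertight periosteal and endosteal STL surfaces are exported for the
   slicer.
3. **Densitometry** -- the mean trabecular bone volume fraction
   $\overline{BV}/TV = \sum GV_{1064} \,/\, (1064 \cdot \sum GV_B)$
   over the spongiosa region.
4. **Calibration** -- a bone power law $E_{\mathrm{eff}} = E_{\mathrm{bone}}
   \rho^k$ converts BV/TV to an equivalent Young's modulus, and an
   empirically fitted gyroid-infill curve $E = a\rho^g$ is inverted to find
   the slicer infill percentage that reproduces that modulus in printed PLA.
5. **Mechanical testing** -- ultimate force and maximum-$R^2$ spring
   stiffness from force--displacement records of stance-type compression
   tests, with group summaries (mean $\pm$ SD and mean-curve bands).

## Models and assumptions

### Grey-value calibration

The 0--1064 scale is inherited from quantitative CT practice: a grey value
is interpreted as 1064 times the local bone fraction. The package maps
user-supplied air and bone reference grey values linearly onto that range
and clips; no auto-detection is attempted, and the map is assumed linear in
attenuation. Whether the underlying scanner scale is linear in attenuation
or in ash density is not resolvable from the data this package sees -- the
linear map is an explicit assumption.

### Bone power law

`power_law()` defaults to $E_{\mathrm{bone}} = 6000$ MPa and $k = 2$, a
mid-range Gibson--Ashby-type fit to published modulus--density data over
the 0--40% density range relevant here. At $\rho = 0.158$ it gives 149.8
MPa. Published modulus--density fits vary widely; over this narrow density
range most parameter choices give nearly the same curve, so no uncertainty
propagation is attempted beyond an extrapolation flag on recommendations.

### Gyroid infill calibration

Printed gyroid cubes at 10/20/40% infill (30 mm edge) provide measured
moduli (bundled as `reference_gyroid_points()`: 24.73, 89.91, 288.79 MPa).
`fit_gyroid_curve()` fits $\log E$ on $\log \rho$ by ordinary least
squares -- means only; the reported spreads are stored for plotting, since
the calibration curve is drawn through the mean moduli. The graphical
look-up between curves is replaced by analytic inversion:
`match_infill()` computes $\rho = (E/a)^{1/g}$ and rounds to the nearest
integer percent (ties up), because slicer infill is specified in integer
percent. Inverting at the bundled foam moduli reproduces the published
assignments of 12% (35.6 MPa), 16% (60 MPa) and 27% ($\sim$150 MPa); the
published 7% for the softest foam (9.06 MPa) does **not** follow from this
inversion, which yields 6% -- a documented discrepancy in the source
material. Likewise the bundled grey-value sums for the human femora are
mutually inconsistent with the BV/TV definition (an apparent
units/exponent typo) and are therefore never used numerically; only the
BV/TV percentages are.

### Spring stiffness

Compression curves of printed bones show a toe region at low load while
the contact area adapts. `spring_stiffness()` starts the analysis range at
the first sample with force $\ge$ 10% of the ultimate force (a curvature
detector would be less reproducible than a force threshold), ends it at
the force maximum (post-failure samples are ignored), and searches all
contiguous windows with a stride of one sample. Unconstrained $R^2$
maximization degenerates to near-two-point windows, so windows must span
at least 20% of the analysis-range displacement (and contain at least 3
samples, the minimum for a meaningful $R^2$). Ties in $R^2$ within
$10^{-9}$ go to the larger displacement span, then to the earlier start;
the tolerance exists because a noiseless straight line makes every window
fit exactly up to floating-point rounding. Cube moduli use the same
machinery on engineering stress--strain ($\sigma = F/L^2$,
$\varepsilon = u/L$), so a cube's modulus is the force--displacement slope
divided by the edge length.

## Key parameters

| parameter | where | default | why |
|---|---|---|---|
| `air_value`, `bone_value` | `rescale_grayscale()` | user-supplied | calibration references are scanner-specific |
| working resolution | `working_resolution_factor()` | largest dim $\le$ 512 | speed; segmentation is resolution-robust at this scale |
| `threshold` | `segment_femur()` | Otsu | no universal grey threshold exists; fixed value overridable |
| `peel_radius` | `split_cortex_spongiosa()` | 5 voxels | a human femoral cortex at the working resolution |
| `sigma` | `smooth_mask()` | 1 mm | clean borderlines without eroding the thin cortex |
| `e_bone`, `k` | `power_law()` | 6000 MPa, 2 | mid-range fit to published modulus--density data |
| `toe_fraction` | `spring_stiffness()` | 0.10 | deterministic toe cut-off |
| `min_window_fraction` | `spring_stiffness()` | 0.20 | guards against degenerate max-$R^2$ windows |

A caveat on the Otsu default: Otsu separates the two dominant histogram
modes. On a volume whose trabecular interior is much darker than the
cortex (as in the synthetic phantoms below), the optimum can fall between
trabecular bone and cortex instead of between air and bone, leaving a
hollow "whole bone" mask. Such volumes need a fixed threshold between the
air and trabecular grey levels -- the pipeline accepts any numeric
`threshold` for this reason.

## Numerical and design choices

* **Connectivity.** 26-connected foreground with 6-connected background
  throughout -- the standard complementary pairing that avoids topological
  paradoxes in component labelling and hole filling.
* **Morphology.** Euclidean ball structuring elements, implemented through
  an exact truncated squared distance transform (per-axis offset sweeps
  capped at the radius, so cost grows with the radius, not the grid).
  Closing operates on a padded grid: without padding, a dilation that
  reaches the volume border deletes the outside background there and the
  subsequent erosion under-erodes. Distances are measured in voxel units;
  working volumes are assumed near-isotropic.
* **Cortex/interior split.** Closing (radius = `peel_radius`) seals small
  cortical gaps before erosion; the largest interior component is kept and
  intersected with the bone so that cortex and interior partition the bone
  mask exactly. An erosion that empties the mask is an error suggesting a
  smaller `peel_radius`.
* **Spongiosa.** `bone - cortex` with 6-connected cavity filling, so the
  spongiosa is the full endosteal cavity (the role the grey-value
  inversion step plays in an interactive workflow). The cortex is
  intersected with the filled bone first; cortex and spongiosa are
  disjoint by construction.
* **Surfaces.** Masks are triangulated as exact voxel-boundary (cuberille)
  surfaces: every boundary face contributes two outward-oriented
  triangles on the voxel corners. Meshes are watertight by construction
  and enclose exactly the mask volume. An iso-surface at 0.5 of the 0/1
  field was rejected: its crossings sit at edge midpoints, so it encloses
  only about 1/6 of an isolated voxel's volume and systematically
  undercuts thin structures, violating the volume contracts the exporter
  must meet. Stair-step artefacts are addressed where they belong, by
  smoothing the mask before export.
* **Rounding.** Infill percentages round half-up to integers and clamp to
  [1, 100]; a zero target modulus therefore clamps to 1% and is flagged
  extrapolated.
* **Degenerate inputs.** Constant volumes cannot be thresholded; empty
  masks have no surface; curves need 10 samples before the force maximum
  and a nonzero displacement span between toe and peak. All are explicit
  errors rather than silent results.

## The synthetic generators

`femur_phantom()` emulates what the pipeline needs from a femur scan, not
femoral anatomy: a stack of circular cross-sections (shaft, drifting
narrower neck, spherical head) defines the outer profile; the cortical
shell (voxels within the cortical thickness of the boundary) is set to
grey 1064; the trabecular interior is a homogeneous mean grey
$1064 \cdot BV/TV$ plus clipped Gaussian noise; distractor blobs
(embedding plate, holder) exercise the largest-component cleanup. Truth
masks come from the same geometric construction, so segmentation accuracy
is measured against an exact reference. Trabecular grey values are
homogeneous rather than structured because BV/TV depends only on the ROI
mean -- trabecular architecture is irrelevant to every computation in
scope. Consequently, passing phantom tests demonstrates correctness of
the *computations*, not robustness to real trabecular texture, partial
volume effects, beam hardening or metal artefacts.

`make_test_curve()` generates stance-type compression records: a
power-law toe joining the linear branch continuously in value and slope,
a peak at the ultimate force placed exactly on a sample, then linear
softening, plus seeded Gaussian force noise. Because noise perturbs the
realized peak, the generator reports the realized maximum as the
ground-truth ultimate force and the noiseless slope as the ground-truth
stiffness. `make_cube_curve()` does the same for cube tests, where the
true slope is $E \cdot L$.

Default phantom dimensions ($64 \times 64 \times 96$ at 1 mm) and curve
sampling (0.01 mm steps) keep a full phantom-to-infill run and the
100-curve stiffness study at interactive speeds; both are package
defaults chosen to exercise every code path at meaningful sizes.

## Worked example

```{r example}
# phantom scan with known ground truth
ph <- femur_phantom(bvtv = 0.158, seed = 1)

# segment (fixed threshold: trimodal phantom histogram, see above)
seg <- segment_femur(ph$volume, threshold = 80, peel_radius = 3)
export_surfaces(seg, file.path(tempdir(), "femur"))

# densitometry on the spongiosa mask
b <- bvtv(ph$volume, seg$spongiosa)

# calibration: BV/TV -> modulus -> infill
cal <- fit_gyroid_curve(reference_gyroid_points())
rec <- infill_from_bvtv(b, cal = cal)
print_parameter_report(rec)

# mechanical test analysis
tc <- make_test_curve(k = 1600, f_ult = 8677, toe_span = 0.5,
                      noise_sd = 0.01, seed = 2)
fit <- spring_stiffness(tc$curve)
plot(fit)
```

## Known limitations

* No CT reconstruction, beam-hardening or Hounsfield calibration; volumes
  must already be on (or calibratable to) the bone-fraction scale.
* DICOM support covers explicit-VR little-endian uncompressed 16-bit
  monochrome series -- the common case for reconstructed micro-CT exports --
  not the full DICOM zoo. TIFF stacks carry no spacing metadata, so spacing
  must be supplied on read; MetaImage is the lossless interchange format.
* One isotropic modulus--density law; no anisotropy or site-specific
  fitting, and no slicing or G-code generation -- the print-parameter
  report ends where the slicer begins.
* The trabecular interior is exported as a closed cavity to be filled by
  slicer infill; trabecular micro-architecture is deliberately not meshed.
* Fracture-pattern classification and any physically measured quantity of
  a printed bone are outside the package: they require a printer and a
  test rig.
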