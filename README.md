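# bonesurro

Design of mechanically calibrated, 3D-printable femoral bone surrogates in R.

Patient-specific femur replicas can be FDM-printed cheaply, but they are only
useful for biomechanical testing (implants, screws, fracture fixation) if the
printed part is *mechanically* calibrated: the cortex printed solid, and the
trabecular interior replaced by a slicer infill whose stiffness matches the
bone it stands in for. `bonesurro` implements that workflow:

* **Volume I/O** — DICOM series, multi-page TIFF stacks and MetaImage
  (`read_volume()`, `write_volume()`), linear grey-value calibration to a
  0–1064 bone-fraction scale (`rescale_grayscale()`), block-mean
  downsampling and QC midplanes.
* **Segmentation** — global threshold with largest-component cleanup,
  morphological cortex/spongiosa separation, manual-overlay hook, mask
  smoothing, cavity filling, and watertight periosteal/endosteal STL export
  (`segment_femur()`, `export_surfaces()`).
* **Densitometry** — mean trabecular bone volume fraction
  `BV/TV = ΣGV_1064 / (1064 · ΣGV_B)` over the spongiosa (`bvtv()`).
* **Calibration** — the bone power law `E_eff = E_bone · ρ^k` (defaults
  6000 MPa, k = 2; `power_law()`), a log-log least-squares fit of gyroid
  cube tests `E = a · ρ^g` (`fit_gyroid_curve()`), and analytic inversion to
  an integer infill percent (`match_infill()`, `infill_from_bvtv()`), plus
  the fixed slicer print-parameter report (`print_parameter_report()`).
* **Mechanical testing** — ultimate force and maximum-R² spring stiffness of
  force–displacement curves with toe-region handling
  (`spring_stiffness()`), and group summaries with mean-curve SD bands
  (`summarize_group()`).
* **Synthetic fixtures** — seeded femur phantoms and compression curves with
  exact ground truth (`femur_phantom()`, `make_test_curve()`,
  `make_cube_curve()`), so every stage is testable without a scanner or a
  test rig.

A thin command-line wrapper ships at
`system.file("cli", "bonesurro", package = "bonesurro")` with subcommands
`convert`, `segment`, `bvtv`, `recommend-infill`, `analyze-test`,
`make-phantom`, `make-curve`.

## Worked example

```r
library(bonesurro)

# a femur-like scan with known ground truth (BV/TV = 0.158)
ph  <- femur_phantom(bvtv = 0.158, seed = 1)
seg <- segment_femur(ph$volume, threshold = 80, peel_radius = 3)
b   <- bvtv(ph$volume, seg$spongiosa)
b
#> <bvtv_result>
#>   sum of grey values (0-1064): 2,175,746
#>   ROI voxels:                  11,983
#>   mean BV/TV:                  0.1706  (17.1%)

cal <- fit_gyroid_curve(reference_gyroid_points())
cal
#> <gyroid_calibration> E = a * rho^g fitted to 3 cube tests
#>   a = 1496 MPa,  g = 1.773
#>   calibrated modulus range: [24.73, 288.8] MPa

infill_from_bvtv(b, cal = cal)
#> <infill_recommendation>
#>   BV/TV:           0.1706  (17.1%)
#>   target modulus:  174.72 MPa
#>   gyroid infill:  30%
#>   provenance:      bvtv_via_power_law
```

The BV/TV measured through the full pipeline (17.1%) sits close to the
phantom's constructed 15.8%; smoothing of the thin cortical shell accounts
for most of the difference (segmenting with `sigma = 0` lands within one
infill percent of the 27% that the constructed BV/TV implies directly). The
recommendation chain reads: a trabecular fraction of 0.171 is mechanically
equivalent to ~175 MPa under the bone power law, which the fitted gyroid
curve maps to a 30% infill.

Mechanical test records are analyzed the same way whether they come from a
file (`load_curve("test.csv")`) or the generator:

```r
tc  <- make_test_curve(k = 1600, f_ult = 8677, toe_span = 0.5,
                       noise_sd = 0.01, seed = 2)
spring_stiffness(tc$curve)
#> <stiffness_fit>
#>   ultimate force F_ult: 8889.32 N at u = 5.66 mm
#>   spring stiffness k:   1601.75 N/mm  (R^2 = 0.998487)
#>   fit window: samples 77-566, u in [0.76, 5.65] mm
```

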