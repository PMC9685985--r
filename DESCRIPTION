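Package: bonesurro
Title: Design and Mechanical Calibration of 3D-Printable Femoral Bone Surrogates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning calibrated computed-tomography volumes of femoral
    bones into mechanically calibrated, 3D-printable surrogates. Provides
    volumetric image input/output (DICOM series, multi-page TIFF stacks,
    MetaImage) with grey-value calibration to a 0-1064 bone-fraction scale,
    a morphological cortex/spongiosa segmentation pipeline with watertight
    STL surface export, trabecular bone volume fraction (BV/TV) densitometry,
    a power-law mapping from bone density to an equivalent Young's modulus,
    log-log least-squares calibration of gyroid-infill stiffness from cube
    compression tests with analytic infill-density matching, and analysis of
    compression-test force-displacement curves (ultimate force, maximum-R^2
    spring stiffness, group summaries). Synthetic femur phantoms and test
    curves with known ground truth support validation of every stage.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
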