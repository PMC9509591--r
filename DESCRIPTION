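Package: qct2e
Title: Phantom-Calibrated Conversion of CT Scans to Voxel-Wise Young's
    Modulus Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts computed-tomography image series into voxel-wise
    Young's modulus maps suitable for bone finite-element modelling.
    Provides phantom-based calibration of stored DICOM grayscale values
    against manufacturer-defined quantitative CT (QCT) densities, linear
    conversion of QCT density to wet apparent density, and a three-branch
    piecewise material law assigning a constant low modulus to air, a
    density power law to trabecular bone and a constant modulus to
    cortical bone.  Includes readers and writers for DICOM series, NIfTI
    and MetaImage volumes, profile-line and cylindrical ROI sampling with
    trilinear interpolation, synthetic phantom and bone-volume generators
    with closed-form ground truth, material binning for finite-element
    export, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    RNifti,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
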