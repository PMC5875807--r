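Package: flipflow
Title: T1-Weighted Inflow ('Flip-Flop') Flow MRI: Simulation and Velocity Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Forward signal simulation and quantitative processing for
    inflow-sensitive multi-slice spin-echo flow MRI of slow laminar flow,
    as used for xylem sap-flow imaging in plants. Provides closed-form
    voxel signal models for flip/flop slice-ordering acquisitions
    (concentrated and distributed repetition time), an independent
    discrete spin-transport oracle, Poiseuille and truncated-Poiseuille
    velocity averages, a synthetic flow-phantom image generator with a
    two-tube validation bench preset, a subtraction/segmentation/multi-TR
    fitting pipeline that estimates the peak velocity and calibrates flow
    maps in absolute units, and the fixed-time SNR model giving the
    optimal repetition time TR = T1/2. Images are read and written as
    NIfTI-1 with JSON sidecars.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
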