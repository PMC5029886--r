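Package: calbold
Title: Calibrated Dual-Echo ASL BOLD Analysis of Oxygen Extraction and Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of combined hypercapnia/hyperoxia calibrated
    MRI experiments acquired with dual-echo pseudo-continuous arterial spin
    labeling (pCASL). Includes a synthetic-data generator for ground-truth
    parameter maps, respiratory traces and annotated dual-echo series;
    extraction of end-tidal gas values with filter-attenuation and water-vapor
    corrections; GLM estimation of per-condition S0 and R2* with dual-echo
    fitting, median filtering and exclusion masking; CBF quantification with
    slice-dependent post-labeling delay and hyperoxic blood-T1 correction;
    voxelwise solution of the generalized calibration model for the BOLD
    calibration parameter M, resting oxygen extraction fraction, oxygen
    delivery and absolute CMRO2; test-retest reproducibility statistics
    (within/between-subject CV, coefficient of repeatability, Bland-Altman);
    and systematic/random error-sensitivity analyses of the calibration model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
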