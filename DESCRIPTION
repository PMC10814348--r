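Package: hp13c
Title: Dynamic Hyperpolarized 13C Pyruvate MRI Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dynamic hyperpolarized [1-13C]pyruvate
    metabolic MRI of the brain. Provides seeded synthetic phantoms and
    multichannel dynamic datasets; multichannel preprocessing (noise-covariance
    estimation, Cholesky prewhitening, pyruvate-weighted coil combination,
    zero-order phasing, higher-order SVD denoising, SNR-thresholded AUC maps);
    voxelwise inputless two-site kinetic modeling of pyruvate-to-lactate (kPL)
    and pyruvate-to-bicarbonate (kPB) rate constants with residual-based error
    maps; pyruvate inflow percentage and acquisition-delay simulation;
    patch-based hemispheric asymmetry scoring of kinetic maps; oriented-box
    prescription coverage with Dice overlap; and frequency-referencing,
    excitation-response and injection quality-control utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
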