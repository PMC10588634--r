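Package: littsim
Title: Axisymmetric Simulation of Laser Interstitial Thermal Therapy
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Numerical model of laser interstitial thermal therapy (LITT)
    in brain tissue with a water-cooled diffusing-tip applicator. Couples
    radiative transfer at 1064 nm or 980 nm (weighted-photon Monte Carlo
    and the P1 diffusion approximation), the Pennes bioheat equation on a
    two-dimensional axisymmetric finite-volume grid with an isothermal
    cooled-catheter boundary, and Arrhenius thermal-damage integration
    with ablation-boundary extraction. Includes proton-resonance-frequency
    (PRF) MR-thermometry utilities for converting phase-image series to
    temperature maps and comparing simulated against measured temperature
    time-courses, plus a synthetic thermometry-series generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    RNifti,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
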