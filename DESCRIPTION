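Package: mtsms
Title: Motion-Resolved Multiparametric Cardiac MRI by Simultaneous
    Multislice Multitasking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and reconstruction framework for non-ECG, free-breathing,
    motion-resolved myocardial T1/T2 mapping across three simultaneously excited
    short-axis slices. Provides the T2prep-IR dual-flip-angle FLASH signal model
    and Bloch dictionary, a dynamic digital left-ventricle phantom with cardiac
    and respiratory motion, golden-angle radial simultaneous-multislice
    (CAIPIRINHA phase-cycled) encoding operators, self-gated cardiac/respiratory
    binning, low-rank tensor completion with higher-order SVD factor extraction,
    wavelet-regularized spatial-factor recovery, two-step voxelwise T1/T2/B1+
    fitting, and the agreement and repeatability statistics used in quantitative
    cardiac MRI (ICC, Bland-Altman, coefficients of variation, AHA 16-segment
    analysis, SNR efficiency).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    RNifti
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
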