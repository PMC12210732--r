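Package: thermotol
Title: Critical Heat-Injury Temperatures of Plant Leaves from Thermal and
    Fluorescence Curves
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Derives critical heat-injury temperatures of plant leaves from
    measured temperature-response curves. Analyses differential scanning
    calorimetry (DSC) thermograms of intact leaves heated at a constant rate,
    extracting the endotherm and exotherm peak temperatures (T_endo, T_exo)
    and the onset of denaturation (T_init) as the intersection of two line
    segments selected by a sliding-band R-squared search; classifies curves
    as vital or heat-killed. Extracts PSII thermotolerance thresholds (T_c,
    T_p, T_pII) from basic chlorophyll fluorescence versus leaf-temperature
    (T-F0) curves. Fits a four-parameter sigmoid to Fv/Fm viability assays to
    obtain LT_10 and LT_50 with a subsampling bootstrap. Includes synthetic
    generators for all three curve types with known ground truth, pooled
    summary statistics and cross-method correlations, plus delimited-text
    input/output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
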