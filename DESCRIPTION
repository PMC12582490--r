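Package: pfasprm
Title: Fragmentation-Guided PRM Quantification of Per- and Polyfluoroalkyl Substances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for targeted quantification of per- and polyfluoroalkyl
    substances (PFAS) by high-resolution parallel reaction monitoring (PRM).
    Provides exact monoisotopic mass and molecular-formula arithmetic, a
    rule-based fragment-ion predictor for six PFAS structural classes
    (perfluorocarboxylic and perfluorosulfonic acids, sulfonamides,
    fluorotelomer sulfonates, ether carboxylic acids and chlorinated
    polyfluoroether sulfonates), extracted-ion-chromatogram integration and
    spectrum annotation, internal-standard calibration with a lack-of-fit
    linearity F-test, signal-to-noise based detection and quantification
    limits, spike-recovery statistics, and a synthetic PRM run generator
    with recorded ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    mzR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
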