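Package: ledams
Title: Isomer Recognition in Ion-Trap Tandem Mass Spectrometry by
    Linear-Equation Deconvolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for recognising and quantifying co-eluting isomers in
    ion-trap HPLC-MS/MS workflows without chromatographic resolution.
    Implements energy-resolved MS/MS (ERMS) breakdown-curve analysis
    (survival yield, product-ion formation and product-ion yield curves),
    linear-equation deconvolution analysis (LEDA) of mixed MS/MS signals
    against characteristic product-ion/reference-ion ratio tables (both
    peak-area and scan-by-scan modes), internal-standard quantitation with
    calibration curves and LOD/LOQ estimation, validation-plot assessment
    of deconvolution accuracy and precision, and first-order plasma
    degradation kinetics with half-life reporting.  A seeded synthetic-data
    generator emulates every required input so the full workflow can be
    exercised and validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
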