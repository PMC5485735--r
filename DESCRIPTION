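Package: metabofinger
Title: Plasma 1H-NMR Metabolic Fingerprinting with OPLS-DA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-group metabolic profiling of 1D 1H-NMR plasma spectra.
    Converts spectra into a fixed scheme of integration regions, applies
    mean-centering and Pareto scaling, screens samples by PCA with
    Hotelling's T2 and distance-to-model (DModX) diagnostics, fits a
    two-class OPLS-DA model with sevenfold cross-validated Q2, S-line
    statistics (p(ctr), p(corr)) and VIP with jack-knife standard errors,
    and selects discriminating variables by the joint univariate
    (Benjamini-Hochberg adjusted t-test), p(corr) and VIP criteria.
    Includes a seedable synthetic-data generator emulating a pediatric
    type 1 diabetes case-control design for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
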