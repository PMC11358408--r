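Package: drydown
Title: Reliability Ranking of Optical and Fluorescence Proxies of Leaf
    Water Status
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for deciding which leaf-level measurements most
    reliably track leaf water status during desiccation. Computes leaf
    water-status quantities (leaf mass decrease, relative water content,
    equivalent water thickness) with species-specific linear
    calibrations, reflectance-derived water and vegetation indices
    (R900/R970, R1000/R1450, the 800-1100 nm reflectance slope, NDVI),
    and chlorophyll-fluorescence parameters (Fv/Fm, PhiPSII at steady
    state, NPQ) from induction-protocol records or traces. At its core
    is a coefficient-of-reliability framework that scores every
    monitored parameter against relative water content over the 100-50%
    window: a coefficient of reliability CR = |slope|*Delta_s / (mean
    absolute residual), a coefficient of sensitivity CS = 100*|slope| /
    |mean|, and a coefficient of inaccuracy CI = 100*(mean absolute
    residual)/|mean|, with ranking, a reliability threshold, per-group
    rank sums, and coefficient-coefficient correlations. A seeded
    synthetic desiccating-leaf generator (drying kinetics, per-parameter
    response shapes, leaf shrinkage, two-component noise, synthetic
    spectra and fluorescence traces) makes the whole pipeline testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
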