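Package: movesync
Title: Identification of Dyadic Movement Synchrony from Motion Energy Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify movement synchronization intervals in dyadic
    motion energy time series using windowed cross-lagged correlation (WCLC)
    and windowed cross-lagged regression (WCLR) with peak-picking on the
    resulting R-squared landscape. Includes motion energy extraction from
    grayscale frame stacks, variance-stabilizing transforms (log(x+1),
    Anscombe), ROI size standardization, natural cubic smoothing splines,
    a synthetic generator of dyadic pulse-train sequences with known
    ground-truth synchronization intervals under three complexity conditions
    (artificial, naturally isolated, naturally embedded analogue), and a
    validation-study layer that scores factorial grids of analysis
    configurations by Cohen's kappa, over-identification rate, and ordinal
    identification-rate classes with Fisher's exact tests, Cramer's V,
    proportional-odds regression and Kruskal-Wallis tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
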