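Package: puffyield
Title: Empirical Emissions Models and Puff Topography Analysis for
    E-Cigarette Yield Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate the total particulate mass (TPM) and nicotine
    delivered to the mouth of an electronic-cigarette user from puffing
    topography recordings.  Fits a log-quadratic TPM concentration surface
    in puff flow rate and duration and a linear nicotine mass-ratio model to
    machine-puffed emissions trials by ordinary least squares, with full
    coefficient diagnostics.  Applies fitted models puff-by-puff to detected
    puffs in flow-rate time series to predict per-session yields, compares
    predictions against repeated playback measurements (slope, Pearson r,
    R-squared), and generates fully synthetic design-grid trials, topography
    sessions, and observed yields so the entire pipeline can be exercised
    end-to-end from a single seed.  Ships a packaged reference coefficient
    set for one pen-style device and e-liquid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
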