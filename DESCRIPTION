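Package: physiocca
Title: Physiological Coupling Topographies and Family-Aware Canonical
    Correlation Analysis for Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how slow respiratory and cardiac dynamics
    couple to the resting-state fMRI global signal and how that coupling
    relates to behavior. Cleans respiratory-belt and pulse-oximetry traces
    and derives respiration volume per time (RVT), windowed envelope,
    respiration variation and instantaneous heart rate on the fMRI frame
    grid; builds per-participant Fisher-z coupling topographies (GSCORR,
    RVTCORR, HRCORR and variants) with group or individual lag
    optimization; maps per-region spatial consistency between topographies
    with two-way random-effects intraclass correlation; and links
    topographies to behavioral batteries through canonical correlation
    analysis with family-structure-respecting permutation inference,
    max-statistic family-wise error control for back-projected weights,
    and family-aware 10-fold cross-validation. A synthetic-cohort
    generator with known ground truth (global loadings, coupling lag and
    map, planted canonical mode, twin-family blocks) makes every stage
    testable end to end without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
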