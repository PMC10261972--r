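Package: sphagspec
Title: Spectral-Library Analysis of Drying Sphagnum Mosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing laboratory spectral libraries of
    peat mosses (Sphagnum) measured over a drying experiment. Converts raw
    spectroradiometer readings to conical-conical reflectance factors, smooths
    spectra with a Savitzky-Golay filter, computes gravimetric moisture content
    from sample masses, and quantifies inter- and intraspecific spectral
    variation: per-wavelength Wilcoxon rank-sum comparisons between measurement
    times, red-edge inflection points, categorical variance decomposition
    (species vs habitat), PCA with Ward hierarchical clustering, and an
    exhaustive two-band Ratio-Index scan regressed on moisture content. Includes
    a seeded synthetic drying-spectra generator so the whole pipeline runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    digest,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
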