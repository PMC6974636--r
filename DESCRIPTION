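Package: lantimass
Title: Modification-Aware Mass Bookkeeping for Lanthipeptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the mass-spectrometric characterisation of
    cross-linked lanthipeptides such as the cinnamycin-like lantibiotics.
    Provides elemental-formula algebra with monoisotopic masses, charged-ion
    m/z prediction for protonated species, derivation of mature, deoxy and
    chemically desulfurised species from a declarative bridge-topology model,
    y-ion fragment ladders implementing the lysinoalanine rearrangement
    observed in MALDI-TOF spectra, ppm-tolerance annotation of observed peak
    lists, and a synthetic peak-list generator for validating the whole
    screening workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
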