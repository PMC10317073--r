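Package: micromaps
Title: Microbiome Maps: Hilbert-Curve Visualization of Metagenomic Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Lays out a reference collection of microbial genomes along a
    space-filling Hilbert curve so that every cell of a square image
    represents one taxon, and colors cells by per-sample relative
    abundance.  Taxa are ordered either by deterministic depth-first
    linearization of a taxonomy tree (making every clade a contiguous
    "microbial neighborhood") or by a condition-anchored labeled ordering
    that blocks taxa by the biological condition in which their mean
    relative abundance is highest.  Supports single-sample, average,
    aggregate, differential and animated maps, neighborhood boundary
    overlays, curve-path overlays, deterministic PNG export, and a
    synthetic community generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    withr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
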