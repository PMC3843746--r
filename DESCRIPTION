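Package: fretcal
Title: Sensitized-Emission FRET Calibration for Clustered Fluorophores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies donor, acceptor and FRET-channel intensities of
    diffraction-limited fluorescent clusters in multi-channel z-stacks,
    converts them to sensitized emission and proximity ratios via spectral
    bleed-through and cross-excitation corrections, calibrates the proximity
    ratio against donor-quenching FRET efficiency with a linear model, and
    turns efficiencies into donor-acceptor separations through the Forster
    equation with acceptor-maturation correction. Also includes a Monte
    Carlo simulator of donor/acceptor labeling on oligomeric rings
    (gamma-TuRC-style geometry), biexponential fitting of TCSPC fluorescence
    decays convolved with a measured instrument response, and a fully
    ground-truthed synthetic-data generator (cell stacks, calibration
    datasets, decay histograms) so every step is testable without microscope
    data.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
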