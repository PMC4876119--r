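Package: microtherm
Title: Temperature Responses of Marine Bacterioplankton Cell Size and
    Nucleic Acid Content
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing warming-incubation experiments on coastal
    bacterioplankton assayed by flow cytometry. Implements automated gating of
    high- and low-nucleic-acid (HNA/LNA) populations from side scatter and
    green fluorescence, bead-relative normalisation, conversion of scatter to
    cell volume, per-bottle summaries, ordinary-least-squares temperature
    response slopes with percent-per-degree and base-pair equivalents,
    growth-rate and Boltzmann-Arrhenius activation-energy estimation, and
    CARD-FISH / ARISA community-structure comparison via Bray-Curtis
    dissimilarity and UPGMA dendrograms. A synthetic-data generator emulates
    the full monthly incubation design with known ground truth so that every
    stage of the pipeline can be validated by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    vegan,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
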