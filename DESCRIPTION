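Package: metallosite
Title: Discriminating Magnesium from Manganese Binding Sites in Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing divalent-metal cofactor sites in protein
    structures. Reads PDB-format coordinate files, locates Mg(II)/Mn(II)
    heteroatoms, extracts a 25-dimensional descriptor of each site (amino-acid
    composition within a radius plus neighbourhood geometry), and fits a Fisher
    linear discriminant from first principles (scatter matrices, closed-form
    discriminant vector, midpoint threshold, Gaussian posteriors) with
    leave-one-out validation and feature-importance interpretation. Also
    simulates and fits pre-steady-state kinetics of primase diribonucleotide
    synthesis (linear, burst and single-exponential models), and generates
    synthetic structure corpora and Gaussian feature corpora for end-to-end
    testing. Tidyverse-native: data frames in, tibbles out, with broom-style
    tidy() and glance() methods and ggplot2 autoplot() for results.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
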