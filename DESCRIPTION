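Package: hfbscan
Title: Hydrophobin Census, Physicochemistry, Phylogeny and Expression Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based mining of typical class I hydrophobins from fungal
    proteomes via cysteine-spacing grammars, with companion tools for the
    downstream characterization steps of a hydrophobin census: ProtParam-style
    physicochemical descriptors (molecular weight, theoretical pI, GRAVY,
    Kyte-Doolittle hydropathy profiles), distance-based neighbor-joining
    phylogenies with bootstrap support, stage-wise relative expression by the
    2^-ddCt method with one-way ANOVA, and water-contact-angle wettability and
    SDS-resilience arithmetic. Ships a synthetic-data generator that plants
    grammar-conforming hydrophobins, atypical 6/7-cysteine variants and decoy
    sequences with known ground truth so the whole pipeline is testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
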