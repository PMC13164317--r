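Package: nbhub
Title: Interactome Overlap, Hub Discovery and Annotation for PML Nuclear Body Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tidyverse-native pipeline for comparing protein-protein
    interaction networks around PML nuclear bodies: reads BioGRID-style
    interaction snapshots, computes interactome overlaps and Venn
    partitions, selects hub proteins by an evidence-filtered multi-core
    rule, clusters the hub network with an MCODE implementation,
    performs hypergeometric over-representation analysis with
    Benjamini-Hochberg correction, and derives consensus liquid-liquid
    phase separation, intrinsic disorder (PPIDR) and physicochemical
    annotations from predictor score tables. A seeded synthetic-data
    module generates every pipeline input with planted ground truth so
    all stages are testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    igraph,
    jsonlite,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
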