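Package: mitokaryo
Title: Comparative Analysis of Fragmented Mitochondrial Karyotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for representing and comparing multichromosomal circular
    mitochondrial genomes ("mt karyotypes") such as the fragmented
    mitogenomes of parasitic lice. Provides a validated data model and text
    format for oriented gene orders over the canonical 37-gene bilaterian
    complement, pairwise karyotype comparison (chromosome homology by
    maximum-weight matching, maximal shared oriented gene clusters,
    split/merger detection, translocated and inverted gene calls), mapping of
    the binary genome-fragmentation character on fixed phylogenies (Fitch
    parsimony origin counting and Mk1/AsymmMk likelihood ancestral state
    reconstruction via Felsenstein pruning), and a seeded simulator of
    karyotype evolution by fission, fusion, translocation and inversion that
    supplies ground truth for every comparison and reconstruction operation.
    Ships worked fixtures for bird lice of the families Menoponidae and
    Laemobothriidae and a one-call reproduction of the associated analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
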