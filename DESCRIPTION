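Package: phylocoevo
Title: Co-Evolution Networks from Phylogenetic Profiles of Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects functionally linked genes from their pattern of presence
    and absence across a panel of bacterial genomes. Orthologs are called by
    bidirectional best hits from all-vs-all protein similarity tables and
    retained with a per-gene adaptive threshold on the identity-times-coverage
    similarity score (mean of the score or of its kernel density). Binary
    phylogenetic profiles are compared with the phi coefficient, weighted by
    the cubed content-based distance of the most distant genome pair in which
    both genes co-occur and by a gene-neighborhood (synteny) factor, and the
    resulting co-evolution network is partitioned with a from-scratch Markov
    Cluster algorithm. A gain/loss simulator on phylogenies generates fully
    specified synthetic panels with planted co-evolving modules for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    data.table,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
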