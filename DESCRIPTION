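Package: engevo
Title: Intron Evolution Analysis for Nematode GHF5 Endoglucanase Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for characterising the exon-intron structure and
    intron evolution of glycoside hydrolase family 5 (GHF5) endoglucanase
    (cellulase) gene families in plant-parasitic nematodes. Provides
    degenerate-primer design by back-translation of conserved peptide motifs
    (with IUPAC ambiguity codes and inosine), in-silico PCR against genomic
    templates, homology-guided intron inference by protein-anchored spliced
    alignment with canonical GT..AG boundaries, projection of introns onto a
    canonical position numbering with half-integer identifiers for novel
    positions, intron phase statistics, and parsimony (Fitch and Dollo)
    superposition of intron presence/absence characters onto a phylogeny.
    A simulator of intron-bearing gene families evolving along a known tree
    supplies ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    IRanges,
    S4Vectors,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
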