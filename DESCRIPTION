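Package: dloopr
Title: Mitochondrial Control-Region Phylogeography Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for phylogeographic analysis of human mitochondrial DNA
    control-region (D-loop) sequences: parsing and calling of rCRS-relative
    variant motifs, motif-based haplogroup classification against an extensible
    clade registry (including the Southern Cone clades D1g, B2l, C1b13 and
    D4h3a5), median-joining haplotype networks with maximum-parsimony
    post-processing, rho-statistic founder-age (TMRCA) estimation under multiple
    clock calibrations, classic-skyline demographic reconstruction, summary
    diversity statistics with Tamura-Nei distances, AMOVA-based pairwise PhiST
    and neighbor-joining dendrograms, in-silico PCR/RFLP typing, and a seeded
    coalescent simulator of control-region datasets with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    seqinr,
    stats,
    tools,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
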