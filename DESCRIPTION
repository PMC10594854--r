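Package: kmerphylo
Title: Alignment-Free Phylogenies from Rank-Transformed 8-mer Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds genome-level evolutionary relationships without sequence
    alignment. All 8-mers are classified by their CG (or TA) dinucleotide
    content into XY0/XY1/XY2 subsets; counts of the CG- or TA-containing
    8-mers are converted to within-set ranks ("relative frequencies"); a
    root-mean-square distance between the rank vectors of two genomes feeds a
    neighbor-joining tree. Also provides the 8-mer subset-spectrum statistics
    (relative motif number histograms, random center, separability) that
    motivate the feature-set choice, and a first-order Markov genome
    simulator with controllable CpG/TpA suppression evolved along a known
    tree under Jukes-Cantor substitution, so the whole pipeline can be
    validated without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    phangorn,
    jsonlite,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
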