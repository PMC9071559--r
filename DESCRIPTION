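Package: numtscope
Title: Structural Decomposition and Evolutionary Analysis of Nuclear
    Mitochondrial DNA Insertions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize large nuclear insertions of mitochondrial
    DNA (numts) against a circular organelle reference genome: k-mer anchored
    synteny-block decomposition and breakpoint classification (repeat-mediated
    recombination versus non-homologous end joining), detection of alternative
    repeat conformations, banded global alignment and variant calling at very
    high (>99%) identity, mutation-spectrum tables with cytosine-context
    (CpG/CHG/CHH) enrichment tests, inference of post-insertion tandem
    duplications from shared derived variants among repeat copies, diagnostic
    SNV based partitioning of long reads into numt- and organelle-derived sets
    with windowed methylation profiles, and a fully seeded numt-genesis
    simulator that provides machine-readable ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
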