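Package: pavpop
Title: Pan-Genome Presence-Absence and Population-Genomic Selection Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the population genomics of a wild-grass pan-genome:
    calling gene presence from assembly alignment hits, classifying genes into
    core/shell/cloud occupancy classes by successive k-means with BIC model
    selection, chi-square tests for subpopulation over- and
    under-representation of genes, windowed nucleotide diversity and Tajima's D
    scans, EHH/iHS haplotype-based selection scans, a Hudson-style coalescent
    simulator with a domestication bottleneck and an empirical pi-ratio sweep
    test, linkage-disequilibrium decay profiling with a Hill-Weir nonlinear
    fit, Kimura two-parameter dating of retrotransposon bursts and LTR
    divergence, junction-spanning-read insertion detection, and mutual-best-hit
    annotation name mapping. Every analysis can be exercised end to end on
    synthetic data generated in-package with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    vcfR,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    optparse
Config/testthat/edition: 3
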