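Package: deepmeth
Title: Deep Bisulfite Amplicon Sequencing Methylation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multiplexed 454-style bisulfite amplicon
    sequencing: MID-tag demultiplexing, bisulfite-aware pairwise alignment
    against in silico converted reference loci, QC filtering on sequence
    identity and CpH conversion efficiency, per-CpG and single-molecule
    (epiallele) methylation quantification, and cross-method concordance
    statistics (Bland-Altman limits of agreement, regression, deviation
    congruence, coverage thresholds) against bulk pyrosequencing levels.
    Includes a synthetic read generator with known ground truth emulating
    homopolymer errors and incomplete bisulfite conversion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
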