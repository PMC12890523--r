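Package: cfmtdna
Title: Analysis of Circulating Cell-Free Mitochondrial DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising circulating cell-free mitochondrial DNA
    (CCF-mtDNA) from plasma sequencing and droplet digital PCR experiments.
    Provides a NUMT-aware scan of the mitochondrial genome computing the
    per-position minimum Hamming distance against the nuclear genome for
    ddPCR target selection, cfDNA fragment-size analysis from paired-end
    alignment records, low-frequency heteroplasmy calling with explicit
    coverage, allele-fraction and strand criteria, plasma-versus-tissue SNP
    matching for tissue-of-origin inference, Poisson-corrected droplet
    digital PCR quantification, and a targeted-metabolomics workflow (KNN
    imputation, log2 autoscaling, NIPALS PLS-DA with leave-one-out Q2, VIP
    scores, volcano filtering and pathway fractional-impact scores).
    Includes a synthetic-data generator emulating every input the pipeline
    consumes so all stages are testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    Rcpp,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
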