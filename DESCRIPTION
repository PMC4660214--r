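Package: itdseq
Title: Detection, Annotation and Quantification of Internal Tandem
    Duplications from Short-Read Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering internal tandem duplications (ITDs) in
    short-read sequencing data of a single target locus, modeled on the
    recurrent in-frame duplications that cluster in the terminal coding exon
    of the X-linked BCOR gene in pediatric clear cell sarcoma of the kidney.
    The package simulates paired-end reads over a configurable minus-strand
    locus, aligns them with a soft-clipping semi-global aligner, reconstructs
    tandem duplications and non-templated junctional insertions from clipped
    subsequences corroborated by discordant mate-pair coverage peaks,
    annotates calls with normalized genomic, coding-DNA and protein
    descriptions, applies tumour/normal somatic filters, estimates mutant
    versus wild-type transcript fractions with an effective-length-corrected
    expectation-maximization, and reproduces an FPKM filtering, Spearman/UPGMA
    clustering and signal-to-noise ranking recipe for expression matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
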