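Package: uvbsrna
Title: Small RNA-Seq Analysis of a Two-Condition miRNA Study
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A self-contained small RNA sequencing analysis chain for
    two-condition plant miRNA studies: raw-read quality control and
    adapter trimming into 18-30 nt unique tags, annotation-based tag
    classification, known-miRNA identification by bounded-mismatch
    matching against a mature-miRNA database, novel-miRNA discovery by
    hairpin folding of unannotated loci under a stacked-pair energy
    model, plant miRNA target prediction under the positional
    mismatch-scoring rules of Allen et al. with a duplex
    minimum-free-energy ratio test, reads-per-million normalization with
    log2 fold-change and ratio-based regulation calls, and closed-form
    phenotype utilities (total chlorophyll from absorbances, delta-delta-Ct
    relative expression). Includes a synthetic-data generator that emulates
    a UVB-versus-control study design with known ground truth, and a
    pipeline driver that reproduces the study-style summary tables on
    simulated libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
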