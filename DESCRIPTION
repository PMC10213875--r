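Package: sncTrans
Title: Small Non-Coding RNA Annotation and Transgenerational Differential
    Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hierarchical biotype annotation of small non-coding RNA
    (sncRNA) sequencing reads (miRNA, rRNA-derived rsRNA, tRNA-derived
    tsRNA, piRNA, other ncRNA) with a zero-mismatch cascade and a
    one-mismatch genome-filtered rescue step, tsRNA subtype
    classification, Svedberg-ordered rsRNA parent assignment,
    identical-sequence clustering and RPM quantification, a conditional
    negative-binomial exact test with common dispersion for differential
    expression, direction-consistent transgenerational (F1-F3) overlap
    calling, and cross-species seed-anchored homology matching. Includes
    a synthetic-data generator with known truth that emulates a
    multi-lineage, multi-generation sperm sncRNA-seq design plus a
    two-group serum comparison, so the whole pipeline is testable
    end-to-end without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    S4Vectors,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    edgeR,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
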