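Package: csmeth
Title: Cell-Subset Specific Methylation from Single-Cell Bisulfite Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers cell-subset specific methylation (CSM) from read-level
    single-cell bisulfite sequencing calls. Extracts 4-CpG segments from
    reads, excludes allele-specific (ASM) and asymmetric (AM) methylation,
    builds candidate regions from bipolar seeds, estimates per region-cell
    beta-binomial priors by empirical Bayes, fits a two-state beta mixture
    model by EM with a likelihood ratio test and Benjamini-Hochberg
    adjustment to call CSM loci, and estimates cell-to-cell methylation
    variance with a non-iterative random-effects (DerSimonian-Laird type)
    estimator with bootstrap confidence intervals. Includes a simulation
    and assessment harness, a synthetic-methylome generator, and
    downstream co-methylation module clustering and genomic-feature
    enrichment utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    jsonlite
Config/testthat/edition: 3
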