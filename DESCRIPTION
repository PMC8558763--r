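Package: xdosage
Title: Allele-Specific X-Chromosome Dosage Compensation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for allele-resolved analysis of X-chromosome dosage
    compensation from hybrid-cross (Mus x Cast) ATAC-seq and single-cell
    RNA-seq allelic count matrices. Implements X-to-autosome dosage
    statistics, allelic-ratio dynamics of chromatin accessibility with
    trajectory clustering and opening-time estimation, per-gene
    X-reactivation and upregulation-erasure kinetics along pseudotime, and
    maximum-likelihood inference of two-state (telegraph) transcriptional
    burst kinetics under the Poisson-beta model. Ships synthetic allelic
    count generators with full ground truth so every stage of the pipeline
    is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
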