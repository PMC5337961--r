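Package: snprisk
Title: Functional Prioritization of Regulatory Risk SNPs and Genetic Risk
    Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Expands GWAS tag SNPs to linkage-disequilibrium proxies (two-locus
    r-squared from phased haplotypes or by EM from unphased genotypes), annotates
    proxies against coding exons, transcription-start-site windows and histone-mark
    intervals, scores allele-specific disruption of transcription-factor binding
    motifs with scaled position-weight-matrix scores, applies a three-condition
    regulatory prioritization (mark overlap, strong motif disruption, expressed
    target gene), and evaluates prioritized SNP sets in case-control cohorts via
    unweighted genotype scores, logistic regression, cross-validated AUC, and
    categorical/continuous net reclassification improvement and integrated
    discrimination improvement with asymptotic inference. Includes a deterministic
    synthetic-data generator (LD-blocked haplotypes, additive-logit disease model,
    mark intervals with controlled overlap, planted motif-disruption sites) so the
    whole pipeline is testable without external genomic resources.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
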