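Package: ldstack
Title: Prioritization of GWAS Signals by Linkage-Disequilibrium Consistency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of genome-wide association summary statistics to
    separate regions of "stacked", mutually supporting association signals
    from isolated significant SNPs that are more likely genotyping or
    sequencing artifacts. Significant SNPs are chained into genomic regions,
    split into same-effect-direction signal groups linked by linkage
    disequilibrium (r-squared) to a top SNP, and each group is scored by the
    mean absolute error between observed -log10 p-values and those predicted
    from LD to the top SNP. Regions containing at least one consistent signal
    are prioritized. Includes the minimal upstream steps (genotype quality
    control, covariate-adjusted additive logistic association, Hardy-Weinberg
    exact test, genomic inflation factor) and downstream steps (region-to-gene
    annotation, tabular outputs) needed to run the method end to end, plus a
    case-control genotype simulator with haplotype-block LD, a planted causal
    variant, and injected artifact SNPs for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
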