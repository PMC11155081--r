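# ldstack

Prioritization of GWAS association signals by linkage-disequilibrium (LD)
consistency.

## The problem

Association scans from small, unbalanced case-control sequencing cohorts —
tens of cases against hundreds of controls, often genotyped by different
pipelines — are littered with isolated, highly significant SNPs caused by
genotyping and calling artifacts. A true common-variant association is
carried on a haplotype: the SNPs in LD with the causal variant form a
"stack" of mutually supporting signals. `ldstack` separates the two. It is
aimed at analysts post-processing per-SNP summary statistics who have
genotypes (or precomputed r²) available for LD.

## The method

Significant SNPs (p < 0.05) are chained into genomic regions (consecutive
significant SNPs ≤ 5 kb apart; regions need ≥ 10 significant SNPs). Within
a region, SNPs of one effect direction (OR > 1 or OR < 1) linked to a top
SNP by r² > 0.4 form a signal group. With s = −log₁₀ p, each member's
expected signal is predicted from its LD to the top SNP,

    ŝ = s_max × r² ,

and the group is scored by the mean absolute error over its K members,

    MAE = Σₖ |sₖ − ŝₖ| / K .

Regions containing at least one group with MAE < 3.0 are prioritized;
isolated significant SNPs cannot form regions and are discarded. The
package also provides the minimal surrounding pipeline: genotype QC
(missingness 10%, MAF 1%, Hardy-Weinberg exact test at 1e-4),
covariate-adjusted additive logistic association, the genomic inflation
factor λ, Manhattan/QQ coordinates, region-to-gene annotation (± 5 kb
flank), and a fully seeded synthetic benchmark generator with
haplotype-block LD, a planted causal variant, and injected artifact SNPs.

## Worked example

```r
library(ldstack)

cfg  <- simulation_config(n_cases = 136, n_controls = 1864, n_blocks = 10,
                          causal_or = 3, n_spike_snps = 20, seed = 7)
sim  <- simulate_gwas(cfg)                                 # 220 variants
assoc <- logistic_assoc_additive(sim$genotypes, sim$phenotype)
scan <- run_cluster_analyzer(assoc, sim$genotypes)
scan
#> LD-consistency prioritization scan
#>   220 SNPs -> 1 region(s), 1 prioritized containing 20 SNP(s)
summary(scan)
#> 1 region(s) from 220 SNPs; 1 prioritized (20 SNPs)
#>
#>   chrom start_bp  end_bp n_snps_total n_snps_significant n_signal_groups
#> 1     1  1000000 1042521           20                 20               5
#>     best_mae top_snp_id    top_snp_p prioritized
#> 1 0.07383982     b1_s10 5.490731e-14        TRUE
genomic_inflation(assoc$p_value)                  # 1.10  (whole scan)
genomic_inflation(scan$prioritized_assoc$p_value) # 40.2  (prioritized SNPs)
```

The one prioritized region is the planted causal block: all 20 of its SNPs
are significant, and its best signal group tracks the ŝ = s_max·r² line to
a mean absolute error of 0.07 log units. None of the 20 injected artifact
SNPs survives (each is alone, far from any LD support). Restricting the
scan to prioritized SNPs concentrates it on signal, so λ jumps from 1.10
to 40.2 — the expected signature of the filter.

A command-line wrapper covering the whole pipeline
(`simulate` / `qc` / `assoc` / `cluster` / `annotate` / `plotdata`) is
installed at `system.file("cli", "ldstack.R", package = "ldstack")`:

```sh
Rscript ldstack.R cluster --assoc scan.assoc --dosages geno.tsv \
        --out-prefix run1
```

Each subcommand writes a JSON run manifest with resolved parameters, input
checksums and output counts.

## Scope notes

LD-consistent false positives (a null LD block whose members drift
significant together) pass the filter by design, and regions of
intrinsically weak LD cannot be prioritized at all. See the methods
vignette (`vignettes/ld-consistency-prioritization.Rmd`) for the model,
design decisions and measured operating characteristics.
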