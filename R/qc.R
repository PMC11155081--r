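#' Hardy-Weinberg equilibrium exact test
#'
#' Conditional exact test on the genotype counts of a biallelic variant: the
#' two-sided p-value sums, over all heterozygote counts attainable given the
#' observed allele counts, the probabilities of configurations no more
#' probable than the observed one. Probabilities are computed in log space
#' from the closed-form conditional distribution
#' `P(h | N, nA) = N! nA! nB! 2^h / (a! h! b! (2N)!)`
#' (h heterozygotes, a and b the two homozygote counts). This is the exact
#' test PLINK applies under `--hwe`; it remains calibrated at the rare-allele
#' margin where the chi-square approximation fails. Monomorphic variants
#' give p = 1.
#'
#' All three arguments are recycled to a common length; the computation is
#' grouped by distinct (N, allele count) so large vectorized sweeps stay
#' cheap.
#'
#' @param n_hom_ref,n_het,n_hom_alt non-negative integer genotype counts.
#' @return exact two-sided p-value(s) in (0, 1].
#' @export
hwe_exact_p <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- max(length(n_hom_ref), length(n_het), length(n_hom_alt))
  a <- rep_len(as.integer(n_hom_ref), n)
  h <- rep_len(as.integer(n_het), n)
  b <- rep_len(as.integer(n_hom_alt), n)
  if (any(a < 0 | h < 0 | b < 0)) stop("genotype counts must be non-negative")
  N <- a + h + b
  if (any(N < 1L)) stop("total genotype count must be >= 1")
  n_alt <- h + 2L * b                      # alt allele count
  minor <- pmin(n_alt, 2L * N - n_alt)     # conditioning is symmetric in alleles
  out <- numeric(n)
  grp <- paste(N, minor)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    Ng <- N[idx[1L]]; mg <- minor[idx[1L]]
    dist <- hwe_het_logprobs(Ng, mg)       # log P for het = hets[i]
    probs <- exp(dist$logp - max(dist$logp))
    probs <- probs / sum(probs)
    for (i in idx) {
      hi <- match(h[i], dist$hets)
      if (is.na(hi))
        stop("heterozygote count ", h[i],
             " unattainable for the observed allele counts")
      p_obs <- probs[hi]
      out[i] <- min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
    }
  }
  out
}

# internal: log conditional probabilities of all attainable heterozygote
# counts given N genotypes and minor-allele count m (0 <= m <= N).
hwe_het_logprobs <- function(N, m) {
  # h has the parity of m and 0 <= h <= m, with (m - h)/2 minor homozygotes
  hets <- seq.int(m %% 2L, m, by = 2L)
  a <- (m - hets) %/% 2L          # minor homozygotes
  b <- N - a - hets               # major homozygotes
  logp <- lfactorial(N) - lfactorial(a) - lfactorial(hets) - lfactorial(b) +
    hets * log(2) + lfactorial(m) + lfactorial(2L * N - m) -
    lfactorial(2L * N)
  list(hets = hets, logp = logp)
}

#' Genotype quality control
#'
#' Applies the standard pre-association filters in a fixed order:
#' non-autosomal variants, then samples with missingness above
#' `sample_miss_max`, then variants with missingness above `geno_miss_max`,
#' then minor allele frequency strictly below `maf_min` ("less than 1%" is a
#' strict cut: MAF exactly 0.01 is retained), then Hardy-Weinberg exact-test
#' p strictly below `hwe_p_min`. Each step's removals are tallied in the
#' report.
#'
#' @param table a [genotype_table()].
#' @param geno_miss_max maximum variant missingness (default 0.10).
#' @param sample_miss_max maximum sample missingness (default 0.10).
#' @param maf_min minimum minor allele frequency (default 0.01, strict).
#' @param hwe_p_min minimum HWE exact p (default 1e-4, strict).
#' @param phenotype optional binary vector (1 = case), required when
#'   `hwe_controls_only = TRUE`.
#' @param hwe_controls_only evaluate HWE in controls only (default `FALSE`:
#'   all samples).
#' @return list with `table` (filtered [genotype_table()]) and `report`, a
#'   list of counts: `n_input_variants`, `n_removed_nonautosomal`,
#'   `n_removed_sample_missing` (samples), `n_removed_geno_missing`,
#'   `n_removed_maf`, `n_removed_hwe`, `n_output_variants`.
#' @export
qc_filter <- function(table, geno_miss_max = 0.10, sample_miss_max = 0.10,
                      maf_min = 0.01, hwe_p_min = 1e-4,
                      phenotype = NULL, hwe_controls_only = FALSE) {
  if (nrow(table$variants) == 0L) stop("empty genotype table")
  if (hwe_controls_only && is.null(phenotype))
    stop("controls-only HWE requires a phenotype vector")
  n_input <- nrow(table$variants)

  auto <- table$variants$chrom %in% AUTOSOMES
  n_nonauto <- sum(!auto)
  tab <- subset_genotypes(table, variants = which(auto))

  smiss <- rowMeans(is.na(tab$dosages))
  keep_s <- smiss <= sample_miss_max
  n_rm_samples <- sum(!keep_s)
  if (!any(keep_s)) stop("all samples removed by sample-missingness filter")
  tab <- subset_genotypes(tab, samples = which(keep_s))
  if (!is.null(phenotype)) phenotype <- phenotype[keep_s]

  vmiss <- colMeans(is.na(tab$dosages))
  keep_v <- vmiss <= geno_miss_max
  n_rm_miss <- sum(!keep_v)
  tab <- subset_genotypes(tab, variants = which(keep_v))

  af <- colMeans(tab$dosages, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf[is.nan(maf)] <- 0
  keep_maf <- maf >= maf_min
  n_rm_maf <- sum(!keep_maf)
  tab <- subset_genotypes(tab, variants = which(keep_maf))

  hd <- tab$dosages
  if (hwe_controls_only) hd <- hd[phenotype == 0, , drop = FALSE]
  if (ncol(hd) > 0L) {
    n0 <- colSums(hd == 0, na.rm = TRUE)
    n1 <- colSums(hd == 1, na.rm = TRUE)
    n2 <- colSums(hd == 2, na.rm = TRUE)
    hwe_p <- hwe_exact_p(n0, n1, n2)
    keep_hwe <- hwe_p >= hwe_p_min
  } else keep_hwe <- logical(0)
  n_rm_hwe <- sum(!keep_hwe)
  tab <- subset_genotypes(tab, variants = which(keep_hwe))

  report <- list(
    n_input_variants = n_input,
    n_removed_nonautosomal = n_nonauto,
    n_removed_sample_missing = n_rm_samples,
    n_removed_geno_missing = n_rm_miss,
    n_removed_maf = n_rm_maf,
    n_removed_hwe = n_rm_hwe,
    n_output_variants = nrow(tab$variants)
  )
  stopifnot(report$n_output_variants ==
              n_input - n_nonauto - n_rm_miss - n_rm_maf - n_rm_hwe)
  list(table = tab, report = report, phenotype = phenotype)
}
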