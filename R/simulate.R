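#' Configuration of the case-control genotype simulator
#'
#' The generator emulates the data regime the prioritization method targets:
#' a small, unbalanced whole-genome case-control cohort (35 cases / 478
#' controls by default, the scale of the motivating study) genotyped at
#' variants organized in haplotype blocks of strong local LD, with one
#' planted causal variant of specified odds ratio and a set of isolated
#' "spike" variants whose phenotype-correlated genotype corruption mimics
#' platform or genotyping artifacts. Defaults: 12 blocks of 20 SNPs with
#' latent adjacent-site correlation 0.95 (dense WGS-like local LD), causal
#' odds ratio 3 per allele (large, as needed for detection at this cohort
#' size), baseline prevalence 1%, and 20 spikes forced to association
#' p-values between 1e-20 and 1e-5 -- the significance range isolated
#' artifacts reach in small platform-confounded WGS comparisons.
#'
#' @param n_cases,n_controls sample counts per class.
#' @param n_blocks number of haplotype blocks.
#' @param snps_per_block SNPs per block; adjacent block SNPs are < 5 kb
#'   apart, blocks are > 50 kb apart.
#' @param block_r2_decay latent correlation between adjacent sites within a
#'   block (0 < decay <= 1); dosage r^2 decays approximately as its square
#'   per step.
#' @param causal_block_index block holding the causal variant (its middle
#'   SNP), or `NA` for no causal variant.
#' @param causal_or per-allele odds ratio of the causal variant.
#' @param baseline_prevalence disease probability at dosage 0.
#' @param n_spike_snps number of injected artifact variants.
#' @param spike_p_range two p-values; each spike's target association
#'   p-value is drawn log-uniformly between them.
#' @param spike_mode `"isolated"` (each spike > 50 kb from everything,
#'   the standard artifact pattern) or `"clustered"` (all spikes inside one
#'   5 kb window sharing block-like LD, a stress pattern whose p-values are
#'   unrelated to LD).
#' @param seed integer seed; the whole generator is deterministic under it.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(n_cases = 35, n_controls = 478, n_blocks = 12,
                              snps_per_block = 20, block_r2_decay = 0.95,
                              causal_block_index = 1, causal_or = 3,
                              baseline_prevalence = 0.01, n_spike_snps = 20,
                              spike_p_range = c(1e-20, 1e-5),
                              spike_mode = c("isolated", "clustered"),
                              seed = 1L) {
  spike_mode <- match.arg(spike_mode)
  stopifnot(n_cases >= 2, n_controls >= 2, n_blocks >= 1,
            snps_per_block >= 1, block_r2_decay > 0, block_r2_decay <= 1,
            causal_or > 0, baseline_prevalence > 0, baseline_prevalence < 1,
            n_spike_snps >= 0, length(spike_p_range) == 2,
            all(spike_p_range > 0), all(spike_p_range < 1))
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 n_blocks = n_blocks, snps_per_block = snps_per_block,
                 block_r2_decay = block_r2_decay,
                 causal_block_index = causal_block_index,
                 causal_or = causal_or,
                 baseline_prevalence = baseline_prevalence,
                 n_spike_snps = n_spike_snps,
                 spike_p_range = sort(spike_p_range),
                 spike_mode = spike_mode, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate haplotype-block genotypes
#'
#' Per block, a latent standard-normal chain with correlation
#' `block_r2_decay` between adjacent sites is generated for each of the
#' 2(n_cases + n_controls) haplotypes and thresholded at allele-frequency
#' quantiles; the two haplotypes of a sample sum to its dosage. Each block
#' draws one allele frequency (uniform in 0.05-0.5) shared by its sites:
#' near-complete LD between two sites is only attainable at equal allele
#' frequencies, so a coherent high-LD block shares its MAF. Blocks are
#' mutually independent and separated by > 50 kb; within a block adjacent
#' SNPs are < 5 kb apart. Deterministic under `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return a [genotype_table()] whose variants carry snp_ids
#'   `b<block>_s<snp>`; the causal variant (middle SNP of the causal block)
#'   is recorded in attribute `causal_snp_id` (or `NA`), and the latent
#'   correlation of each block variant to the causal variant in attribute
#'   `latent_r2_to_causal`.
#' @export
simulate_haplotype_blocks <- function(config) {
  set.seed(config$seed)
  n <- config$n_cases + config$n_controls
  nh <- 2L * n
  m_blk <- config$snps_per_block
  rho <- config$block_r2_decay
  doses <- vector("list", config$n_blocks)
  pos <- vector("list", config$n_blocks)
  block_start <- 1e6
  for (b in seq_len(config$n_blocks)) {
    z <- matrix(rnorm(nh * m_blk), nh, m_blk)
    if (m_blk > 1L) {
      if (rho == 1) {
        z <- matrix(z[, 1L], nh, m_blk)
      } else {
        for (j in 2:m_blk)
          z[, j] <- rho * z[, j - 1L] + sqrt(1 - rho^2) * z[, j]
      }
    }
    # one frequency per block: r^2 -> 1 between two sites requires equal
    # allele frequencies, so a coherent high-LD block shares its MAF
    f <- rep(runif(1, 0.05, 0.5), m_blk)
    hap <- sweep(z, 2L, qnorm(f), `<`) * 1
    doses[[b]] <- hap[seq(1L, nh, 2L), , drop = FALSE] +
      hap[seq(2L, nh, 2L), , drop = FALSE]
    step <- if (m_blk > 1L) round(runif(m_blk - 1L, 500, 4500)) else numeric(0)
    pos[[b]] <- block_start + cumsum(c(0, step))
    block_start <- max(pos[[b]]) + 1e5   # > 50 kb between blocks
  }
  dosages <- do.call(cbind, doses)
  bp <- unlist(pos)
  snp_id <- paste0("b", rep(seq_len(config$n_blocks), each = m_blk),
                   "_s", rep(seq_len(m_blk), config$n_blocks))
  variants <- data.frame(chrom = "1", bp = as.integer(bp), snp_id = snp_id,
                         ref = "A", alt = "C", stringsAsFactors = FALSE)
  tab <- genotype_table(dosages, variants,
                        sample_ids = sprintf("S%04d", seq_len(n)))
  causal_id <- NA_character_
  latent_r2 <- setNames(rep(0, length(snp_id)), snp_id)
  if (!is.na(config$causal_block_index) && config$causal_or != 1) {
    cb <- config$causal_block_index
    cs <- ceiling(m_blk / 2)
    causal_id <- paste0("b", cb, "_s", cs)
    in_blk <- paste0("b", cb, "_s", seq_len(m_blk))
    latent_r2[in_blk] <- rho^(2 * abs(seq_len(m_blk) - cs))
  }
  attr(tab, "causal_snp_id") <- causal_id
  attr(tab, "latent_r2_to_causal") <- latent_r2
  tab
}

#' Assign case-control phenotypes under a logistic disease model
#'
#' Disease risk follows `logit P(case) = alpha + log(causal_or) * dosage`
#' at the causal variant (no causal variant, or `causal_or = 1`, makes the
#' phenotype independent of all dosages). Exact class counts are produced
#' by conditioning on the total: Bernoulli case indicators are resampled
#' (bounded retries) until exactly `n_cases` cases arise. The conditional
#' law given the total depends only on the dosage effect, not on the
#' intercept, so `alpha` is calibrated to make the expected case count
#' equal `n_cases` purely for sampling efficiency -- the case-enriched
#' design this emulates oversamples cases relative to
#' `baseline_prevalence`, and the odds ratio the downstream logistic fit
#' estimates is preserved under such retrospective sampling.
#'
#' @param table a [genotype_table()] from [simulate_haplotype_blocks()].
#' @param config a [simulation_config()].
#' @return integer phenotype vector (1 = case) of length
#'   `n_cases + n_controls`, aligned with `table$sample_ids`.
#' @export
assign_phenotype <- function(table, config) {
  set.seed(config$seed + 1L)
  n <- length(table$sample_ids)
  stopifnot(n == config$n_cases + config$n_controls)
  causal_id <- attr(table, "causal_snp_id")
  eta_g <- rep(0, n)
  if (!is.na(causal_id) && config$causal_or != 1) {
    j <- match(causal_id, table$variants$snp_id)
    if (is.na(j)) stop("causal variant not present in the genotype table")
    g <- table$dosages[, j]
    g[is.na(g)] <- 0
    eta_g <- log(config$causal_or) * g
  }
  # intercept calibrated so E[number of cases] = n_cases (the conditional
  # distribution given the total is invariant to the intercept)
  alpha <- stats::uniroot(function(a)
    sum(plogis(a + eta_g)) - config$n_cases,
    lower = -50, upper = 50, tol = 1e-10)$root
  p <- plogis(alpha + eta_g)
  for (try in 1:10000) {
    y <- rbinom(n, 1L, p)
    if (sum(y) == config$n_cases) return(as.integer(y))
  }
  stop("could not realize the exact case count after bounded retries")
}

#' Inject artifact ("spike") variants
#'
#' Adds `n_spike_snps` variants whose dosages are corrupted in a
#' phenotype-correlated way, calibrated by bisection on the corruption
#' fraction so that each spike's marginal association p-value (score/trend
#' test) lands near a target drawn log-uniformly from `spike_p_range`. In
#' `"isolated"` mode each spike sits > 50 kb from every block and every
#' other spike, starts from an independent binomial genotype, and therefore
#' has near-zero r^2 to all block variants -- the artifact pattern the
#' method is designed to discard. In `"clustered"` mode all spikes fall in
#' one 5 kb window and share a latent LD chain before corruption, a stress
#' pattern where a region can form although p-values carry no relation to
#' LD.
#'
#' @param table a [genotype_table()].
#' @param phenotype binary vector aligned with the table's samples.
#' @param config a [simulation_config()].
#' @return list with `table` (augmented [genotype_table()]) and `truth`, a
#'   `data.frame` with one row per variant: `snp_id`, `label` in
#'   \{`CAUSAL_LINKED`, `NULL_SNP`, `SPIKE`\}, `is_causal`, and `true_r2`
#'   (latent r^2 to the causal variant for block SNPs).
#' @export
inject_spikes <- function(table, phenotype, config) {
  set.seed(config$seed + 2L)
  truth <- synthetic_truth(table, config)
  if (config$n_spike_snps == 0L)
    return(list(table = table, truth = truth))
  n <- length(table$sample_ids)
  y <- as.integer(phenotype)
  k <- config$n_spike_snps
  lo <- log10(config$spike_p_range[1L]); hi <- log10(config$spike_p_range[2L])
  targets <- 10^runif(k, lo, hi)

  last_bp <- max(table$variants$bp)
  if (config$spike_mode == "isolated") {
    spike_bp <- last_bp + 1e5 * seq_len(k)             # > 50 kb apart
    base <- sapply(seq_len(k), function(i)
      rbinom(n, 2L, runif(1, 0.1, 0.3)))
  } else {
    start <- last_bp + 1e5
    spike_bp <- start + round(seq(0, 4500, length.out = k))
    # shared latent chain -> strong mutual LD before corruption
    z <- matrix(rnorm(2L * n * k), 2L * n, k)
    if (k > 1L) for (j in 2:k)
      z[, j] <- 0.98 * z[, j - 1L] + sqrt(1 - 0.98^2) * z[, j]
    f <- runif(k, 0.2, 0.4)
    hap <- sweep(z, 2L, qnorm(f), `<`) * 1
    base <- hap[seq(1L, 2L * n, 2L), , drop = FALSE] +
      hap[seq(2L, 2L * n, 2L), , drop = FALSE]
  }
  spikes <- matrix(NA_real_, n, k)
  for (i in seq_len(k)) {
    g <- calibrate_spike(base[, i], y, targets[i])
    if (is.null(g))
      stop("spike calibration failed for target p = ", targets[i])
    spikes[, i] <- g
  }
  ids <- paste0("spike", seq_len(k))
  variants <- rbind(table$variants,
                    data.frame(chrom = "1", bp = as.integer(spike_bp),
                               snp_id = ids, ref = "A", alt = "C",
                               stringsAsFactors = FALSE))
  out <- genotype_table(cbind(table$dosages, spikes), variants,
                        sample_ids = table$sample_ids)
  attr(out, "causal_snp_id") <- attr(table, "causal_snp_id")
  attr(out, "latent_r2_to_causal") <- attr(table, "latent_r2_to_causal")
  truth <- rbind(truth,
                 data.frame(snp_id = ids, label = "SPIKE",
                            is_causal = FALSE, true_r2 = 0,
                            stringsAsFactors = FALSE))
  truth <- truth[match(out$variants$snp_id, truth$snp_id), , drop = FALSE]
  rownames(truth) <- NULL
  list(table = out, truth = truth)
}

# internal: truth labels for the block variants of a table
synthetic_truth <- function(table, config) {
  ids <- table$variants$snp_id
  causal_id <- attr(table, "causal_snp_id")
  latent <- attr(table, "latent_r2_to_causal")
  r2 <- if (is.null(latent)) rep(0, length(ids)) else
    unname(latent[match(ids, names(latent))])
  r2[is.na(r2)] <- 0
  cb <- if (!is.na(causal_id))
    sub("_s.*$", "", causal_id) else ""
  in_causal_block <- startsWith(ids, paste0(cb, "_")) & nzchar(cb)
  data.frame(
    snp_id = ids,
    label = ifelse(in_causal_block, "CAUSAL_LINKED", "NULL_SNP"),
    is_causal = !is.na(causal_id) & ids == causal_id,
    true_r2 = r2,
    stringsAsFactors = FALSE)
}

# internal: deterministic trend-test p-value (score test of the
# no-covariate additive logistic model); used only for spike calibration
trend_p <- function(g, y) {
  r <- suppressWarnings(cor(g, y))
  if (is.na(r)) return(1)
  2 * pnorm(-abs(r) * sqrt(length(g)))
}

# internal: bisection on the corruption fraction c: a corrupted sample's
# dosage is forced towards its phenotype (cases to 2, controls to 0), the
# signature of differential calling between case and control pipelines;
# increasing c monotonically strengthens the association. Returns the
# corrupted dosage vector, or NULL if the target is unreachable.
calibrate_spike <- function(base, y, target_p, max_iter = 30L) {
  n <- length(y)
  u <- runif(n)
  corrupt <- function(c) {
    g <- base
    g[y == 1L & u < c] <- 2
    g[y == 0L & u < c] <- 0
    g
  }
  lt <- log10(target_p)
  f <- function(c) log10(trend_p(corrupt(c), y)) - lt
  lo <- 0; hi <- 1
  if (f(1) > 0) return(NULL)     # even full corruption too weak
  if (f(0) < 0) return(corrupt(0))
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  corrupt(hi)
}

#' Simulate a full benchmark dataset
#'
#' Composes [simulate_haplotype_blocks()], [assign_phenotype()] and
#' [inject_spikes()] under a single seed.
#'
#' @param config a [simulation_config()].
#' @return list with `genotypes` (a [genotype_table()]), `phenotype`
#'   (integer vector, 1 = case), `truth` (per-variant labels, see
#'   [inject_spikes()]), and `config`.
#' @export
simulate_gwas <- function(config = simulation_config()) {
  blocks <- simulate_haplotype_blocks(config)
  y <- assign_phenotype(blocks, config)
  sp <- inject_spikes(blocks, y, config)
  list(genotypes = sp$table, phenotype = y, truth = sp$truth,
       config = config)
}
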