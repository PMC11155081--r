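# Fixture builders shared across the test files. Everything is generated in
# code; no binary fixtures.

# association data.frame in the package layout
make_assoc <- function(chrom, bp, p, or = 1.5,
                       snp_id = paste0("rs", seq_along(bp)), a1 = "A") {
  if (length(bp) == 0L)
    return(data.frame(chrom = character(), bp = integer(),
                      snp_id = character(), a1 = character(),
                      odds_ratio = numeric(), p_value = numeric(),
                      neg_log_p = numeric(), stringsAsFactors = FALSE))
  df <- data.frame(chrom = rep_len(as.character(chrom), length(bp)),
                   bp = as.integer(bp),
                   snp_id = snp_id, a1 = rep_len(a1, length(bp)),
                   odds_ratio = rep_len(or, length(bp)),
                   p_value = rep_len(p, length(bp)),
                   stringsAsFactors = FALSE)
  df$neg_log_p <- -log10(df$p_value)
  key <- suppressWarnings(as.numeric(df$chrom))
  key[is.na(key)] <- Inf
  df <- df[order(key, df$chrom, df$bp), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# genotype table from a dosage matrix (samples x variants)
make_genotypes <- function(dosages, chrom = "1",
                           bp = seq_len(ncol(dosages)) * 1000L,
                           snp_id = paste0("rs", seq_len(ncol(dosages)))) {
  variants <- data.frame(chrom = chrom, bp = as.integer(bp), snp_id = snp_id,
                         ref = "A", alt = "C", stringsAsFactors = FALSE)
  genotype_table(dosages, variants,
                 sample_ids = paste0("S", seq_len(nrow(dosages))))
}

# a perfectly LD-consistent region fixture: n SNPs in complete LD, p-values
# on the s_hat = s_max * r^2 line (trivially, all identical)
make_perfect_region_inputs <- function(n_snps = 12, p = 1e-6, n_samples = 60) {
  g <- matrix(rep(c(0, 1, 2), length.out = n_samples), n_samples, n_snps)
  geno <- make_genotypes(g, bp = 1000L + 100L * seq_len(n_snps))
  assoc <- make_assoc("1", geno$variants$bp, p, or = 2,
                      snp_id = geno$variants$snp_id)
  list(assoc = assoc, genotypes = geno)
}

# brute-force transitive-closure oracle for region chaining: two significant
# SNPs share a region iff connected through pairs <= max_gap apart
oracle_chain <- function(bp, max_gap) {
  bp <- sort(bp)
  n <- length(bp)
  if (n == 0) return(integer(0))
  adj <- abs(outer(bp, bp, "-")) <= max_gap
  comp <- seq_len(n)
  repeat {
    new_comp <- comp
    for (i in seq_len(n)) new_comp[i] <- min(comp[adj[i, ]])
    if (all(new_comp == comp)) break
    comp <- new_comp
  }
  match(comp, unique(comp))
}

# naive independent MAE oracle (explicit loop, no shared code path)
oracle_mae <- function(s, r2) {
  smax <- s[1]
  for (v in s) if (v > smax) smax <- v
  total <- 0
  for (k in seq_along(s)) total <- total + abs(s[k] - smax * r2[k])
  total / length(s)
}

# independent HWE enumeration oracle: log-space recurrence over heterozygote
# counts, P(h+2)/P(h) = 4ab/((h+2)(h+1)) with a, b the homozygote counts at h
oracle_hwe <- function(n_hom_ref, n_het, n_hom_alt) {
  N <- n_hom_ref + n_het + n_hom_alt
  m <- min(n_het + 2 * n_hom_alt, n_het + 2 * n_hom_ref)   # minor alleles
  hets <- seq(m %% 2, m, by = 2)
  logp <- numeric(length(hets))
  if (length(hets) > 1) {
    for (i in seq_len(length(hets) - 1)) {
      h <- hets[i]
      a <- (m - h) / 2; b <- N - a - h
      logp[i + 1] <- logp[i] + log(4 * a * b) - log((h + 2) * (h + 1))
    }
  }
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

# small PLINK-logistic-dialect file on disk; returns the path
write_plink_assoc_fixture <- function(lines, dir = tempdir()) {
  path <- tempfile("assoc", tmpdir = dir, fileext = ".assoc.logistic")
  writeLines(lines, path)
  path
}
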