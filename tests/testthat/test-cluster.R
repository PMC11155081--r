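test_that("chain_regions reproduces the worked chaining examples", {
  cfg <- cluster_config(max_gap_bp = 5000, min_significant = 3)
  assoc <- make_assoc("1", c(100, 3000, 7900), 0.01)
  regions <- chain_regions(assoc, cfg)
  expect_length(regions, 1L)
  expect_equal(regions[[1]]$start_bp, 100)
  expect_equal(regions[[1]]$end_bp, 7900)

  cfg2 <- cluster_config(max_gap_bp = 5000, min_significant = 2)
  assoc2 <- make_assoc("1", c(100, 3000, 9001), 0.01)
  regions2 <- chain_regions(assoc2, cfg2)
  expect_length(regions2, 1L)   # gap 6001 > 5000 splits off the singleton
  expect_equal(regions2[[1]]$end_bp, 3000)

  # 9 tight significant SNPs below min_significant = 10 -> nothing
  assoc3 <- make_assoc("1", seq(100, 900, by = 100), 0.01)
  expect_length(chain_regions(assoc3, cluster_config()), 0L)
})

test_that("non-significant SNPs neither bridge nor break chains but join all_snps", {
  cfg <- cluster_config(max_gap_bp = 5000, min_significant = 2)
  # significant at 100 and 4000; non-significant at 2000 (inside) and 20000
  assoc <- make_assoc("1", c(100, 2000, 4000, 20000),
                      p = c(0.01, 0.5, 0.01, 0.5))
  regions <- chain_regions(assoc, cfg)
  expect_length(regions, 1L)
  expect_equal(nrow(regions[[1]]$significant_snps), 2L)
  expect_equal(regions[[1]]$all_snps$bp, c(100L, 2000L, 4000L))

  # a non-significant SNP between two far-apart significant SNPs cannot bridge
  assoc2 <- make_assoc("1", c(100, 5100, 10200), p = c(0.01, 0.5, 0.01))
  expect_length(chain_regions(assoc2, cfg), 0L)
})

test_that("chain_regions matches the transitive-closure oracle on random sets", {
  set.seed(21)
  cfg <- cluster_config(max_gap_bp = 5000, min_significant = 1)
  for (rep in 1:40) {
    n <- sample(2:120, 1)
    bp <- sort(sample.int(3e5, n))   # gaps straddle 5 kb
    assoc <- make_assoc("1", bp, 0.01)
    regions <- chain_regions(assoc, cfg)
    got <- rep(NA_integer_, n)
    for (i in seq_along(regions))
      got[assoc$bp %in% regions[[i]]$significant_snps$bp] <- i
    expect_equal(got, oracle_chain(bp, 5000))
  }
})

test_that("chain_regions refuses unsorted input", {
  assoc <- make_assoc("1", c(100, 200), 0.01)
  expect_error(chain_regions(assoc[c(2, 1), ], cluster_config()), "sorted")
})

test_that("predicted -log10 p follows s_hat = s_max * r^2", {
  expect_equal(predicted_neglogp(8, 1), 8)
  expect_equal(predicted_neglogp(8, 0), 0)
  expect_equal(predicted_neglogp(6, 0.5), 3)
  expect_true(is_no_ld_info(predicted_neglogp(6, NA_real_)))
})

test_that("group_mae equals the naive loop oracle and honors edge cases", {
  # exact fit: every point on the line -> MAE 0
  expect_equal(group_mae(c(8, 4, 2), c(1, 0.5, 0.25)), 0)
  # residuals (0, 3) -> MAE 1.5
  expect_equal(group_mae(c(8, 1), c(1, 0.5)), 1.5)
  set.seed(22)
  for (rep in 1:50) {
    k <- sample(1:40, 1)
    s <- runif(k, 0, 20); r2 <- runif(k)
    expect_equal(group_mae(s, r2), oracle_mae(s, r2), tolerance = 1e-12)
  }
  expect_error(group_mae(numeric(0), numeric(0)), "empty")
  expect_true(is_no_ld_info(group_mae(c(8, 4), c(1, NA))))
})

test_that("MAE is reorder-invariant and strictly increases under perturbation", {
  set.seed(23)
  s <- c(9, 6, 4, 2); r2 <- c(1, 0.7, 0.5, 0.3)
  for (rep in 1:10) {
    ord <- sample(4)
    expect_equal(group_mae(s[ord], r2[ord]), group_mae(s, r2),
                 tolerance = 1e-14)
  }
  # pushing one non-top member further from its prediction raises the MAE
  base <- group_mae(s, r2)
  s2 <- s; s2[3] <- s2[3] - 1   # residual |4 - 4.5| -> |3 - 4.5|
  expect_gt(group_mae(s2, r2), base)
})

test_that("signal groups split by OR direction and re-anchor across LD islands", {
  # 5 UP and 5 DOWN SNPs, within-direction r^2 = 1, across ~ 0
  n <- 40
  gA <- rep(c(0, 1, 2, 1), length.out = n)
  gB <- rep(c(2, 0, 1, 1, 0, 2), length.out = n)
  d <- cbind(gA, gA, gA, gA, gA, gB, gB, gB, gB, gB)
  geno <- make_genotypes(d, bp = 1000L + 50L * (1:10))
  assoc <- make_assoc("1", geno$variants$bp, p = 1e-4,
                      or = rep(c(2, 0.5), each = 5),
                      snp_id = geno$variants$snp_id)
  cfg <- cluster_config(min_significant = 10)
  region <- chain_regions(assoc, cfg)[[1]]
  region <- form_signal_groups(region, geno, cfg)
  expect_length(region$signal_groups, 2L)
  expect_setequal(vapply(region$signal_groups, `[[`, "", "direction"),
                  c("UP", "DOWN"))
  expect_true(all(vapply(region$signal_groups,
                         function(g) nrow(g$members), 0L) == 5L))

  # two UP LD islands -> iterative re-anchoring makes two UP groups
  d2 <- cbind(gA, gA, gA, gB, gB, gB)
  geno2 <- make_genotypes(d2, bp = 1000L + 50L * (1:6))
  assoc2 <- make_assoc("1", geno2$variants$bp,
                       p = c(1e-6, 1e-5, 1e-4, 1e-3, 1e-3, 1e-2), or = 2,
                       snp_id = geno2$variants$snp_id)
  cfg2 <- cluster_config(min_significant = 6)
  region2 <- chain_regions(assoc2, cfg2)[[1]]
  region2 <- form_signal_groups(region2, geno2, cfg2)
  expect_length(region2$signal_groups, 2L)
  tops <- vapply(region2$signal_groups, function(g) g$top_snp$snp_id, "")
  expect_setequal(tops, c("rs1", "rs4"))  # strongest SNP of each island
  # every significant SNP in exactly one group
  all_members <- unlist(lapply(region2$signal_groups,
                               function(g) g$members$snp_id))
  expect_setequal(all_members, region2$significant_snps$snp_id)
  expect_false(any(duplicated(all_members)))
})

test_that("every significant SNP lands in exactly one group on random data", {
  set.seed(24)
  for (rep in 1:10) {
    n_snps <- 15
    d <- matrix(sample(0:2, 50 * n_snps, replace = TRUE), 50, n_snps)
    geno <- make_genotypes(d, bp = 1000L + 200L * seq_len(n_snps))
    assoc <- make_assoc("1", geno$variants$bp,
                        p = 10^runif(n_snps, -8, -1.5),
                        or = exp(rnorm(n_snps)),
                        snp_id = geno$variants$snp_id)
    cfg <- cluster_config(min_significant = 5)
    regions <- chain_regions(assoc, cfg)
    for (rg in regions) {
      rg <- form_signal_groups(rg, geno, cfg)
      members <- unlist(lapply(rg$signal_groups, function(g) g$members$snp_id))
      graded <- rg$significant_snps
      expected <- graded$snp_id[or_direction(graded$odds_ratio) != "NEUTRAL"]
      expect_setequal(members, expected)
      expect_false(any(duplicated(members)))
    }
  }
})

test_that("NEUTRAL SNPs (OR exactly 1) are reported but never grouped", {
  inputs <- make_perfect_region_inputs(n_snps = 12)
  assoc <- inputs$assoc
  assoc$odds_ratio[5] <- 1
  region <- chain_regions(assoc, cluster_config())[[1]]
  region <- form_signal_groups(region, inputs$genotypes, cluster_config())
  members <- unlist(lapply(region$signal_groups, function(g) g$members$snp_id))
  expect_false(assoc$snp_id[5] %in% members)
  expect_true(assoc$snp_id[5] %in% region$all_snps$snp_id)
})

test_that("prioritization respects the strict MAE boundary and sentinels", {
  mk_region <- function(maes, sizes = rep(2L, length(maes))) {
    structure(list(chrom = "1", start_bp = 1, end_bp = 2,
                   signal_groups = Map(function(m, k)
                     list(mae = m, members = data.frame(x = seq_len(k))),
                     maes, sizes),
                   prioritized = NA), class = "snp_region")
  }
  cfg <- cluster_config()
  expect_true(prioritize(list(mk_region(c(4.2, 2.9))), cfg)[[1]]$prioritized)
  expect_false(prioritize(list(mk_region(3.0)), cfg)[[1]]$prioritized)
  expect_false(prioritize(list(mk_region(NA_real_)), cfg)[[1]]$prioritized)
})

test_that("prioritization is monotone in the MAE threshold", {
  set.seed(25)
  sim <- simulate_gwas(simulation_config(n_cases = 60, n_controls = 240,
                                         n_blocks = 6, causal_or = 2.5,
                                         n_spike_snps = 5, seed = 25))
  assoc <- suppressMessages(
    logistic_assoc_additive(sim$genotypes, sim$phenotype))
  pri_at <- function(thr) {
    scan <- run_cluster_analyzer(assoc, sim$genotypes,
                                 cluster_config(mae_threshold = thr,
                                                min_significant = 5))
    which(vapply(scan$regions, function(r) isTRUE(r$prioritized), logical(1)))
  }
  lo <- pri_at(1.0); mid <- pri_at(3.0); hi <- pri_at(10.0)
  expect_true(all(lo %in% mid))
  expect_true(all(mid %in% hi))
})

test_that("run_cluster_analyzer returns empty outputs on empty input", {
  assoc <- make_assoc("1", integer(0), numeric(0))
  geno <- make_genotypes(matrix(c(0, 1, 2), 3, 1))
  scan <- run_cluster_analyzer(assoc, geno)
  expect_length(scan$regions, 0L)
  expect_equal(nrow(scan$prioritized_assoc), 0L)
})

test_that("perfect-LD equal-p regions score MAE 0 and prioritize", {
  inputs <- make_perfect_region_inputs(n_snps = 12, p = 1e-6)
  scan <- run_cluster_analyzer(inputs$assoc, inputs$genotypes)
  expect_equal(scan$counts$n_prioritized_regions, 1L)
  g <- scan$regions[[1]]$signal_groups[[1]]
  expect_equal(g$mae, 0)
  expect_equal(nrow(g$members), 12L)
  # top residual is 0 by construction
  expect_equal(g$residuals[g$members$snp_id == g$top_snp$snp_id], 0)
})

test_that("singleton groups carry the sentinel and cannot prioritize", {
  # 10 significant SNPs, mutually unlinked (r^2 ~ 0) -> all singleton groups
  set.seed(26)
  d <- sapply(1:10, function(i) sample(rep(0:2, 20)))
  geno <- make_genotypes(d, bp = 1000L + 50L * (1:10))
  assoc <- make_assoc("1", geno$variants$bp, p = 10^-(2:11), or = 2,
                      snp_id = geno$variants$snp_id)
  scan <- run_cluster_analyzer(assoc, geno)
  expect_equal(scan$counts$n_regions, 1L)
  expect_equal(scan$counts$n_prioritized_regions, 0L)
  maes <- vapply(scan$regions[[1]]$signal_groups, `[[`, 0, "mae")
  expect_true(all(is_no_ld_info(maes[
    vapply(scan$regions[[1]]$signal_groups,
           function(g) nrow(g$members), 0L) < 2])))
})

test_that("scan methods expose summaries, residuals and plot coordinates", {
  inputs <- make_perfect_region_inputs()
  scan <- run_cluster_analyzer(inputs$assoc, inputs$genotypes)
  expect_output(print(scan), "1 prioritized")
  st <- summary(scan)
  expect_s3_class(st, "summary.cluster_scan")
  expect_equal(nrow(st), 1L)
  res <- residuals(scan)
  expect_equal(nrow(res), 12L)
  expect_true(all(res$residual == 0))
  pdf(NULL)
  man <- plot(scan)
  dev.off()
  expect_equal(nrow(man), nrow(inputs$assoc))
})
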