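#' Configuration for region clustering and consistency scoring
#'
#' Defaults reproduce the method's published operating point: significant
#' SNPs are those with p < 0.05; significant SNPs within 5 kb of one another
#' chain into one region; regions need at least 10 significant SNPs; signal
#' groups require r^2 > 0.4 to the top SNP; a region is prioritized when
#' some group's MAE is below 3.0. All threshold comparisons are strict
#' inequalities.
#'
#' @param p_threshold significance cut on the association p-value.
#' @param max_gap_bp maximum distance (bp) between consecutive significant
#'   SNPs in one region.
#' @param min_significant minimum number of significant SNPs per region.
#' @param r2_threshold LD cut for signal-group membership (exclusive).
#' @param mae_threshold prioritization cut on the group MAE (exclusive).
#' @param log_base base of the -log(P) transform (10, the Manhattan-plot
#'   convention).
#' @param min_group_size smallest signal group that counts towards
#'   prioritization. A single SNP carries no evidence about LD/p-value
#'   consistency (its MAE is identically 0), so singleton groups are
#'   reported but treated as unscoreable; set to 1 to let them prioritize.
#' @param significant_only_mae when `TRUE` (default) only significant SNPs
#'   enter signal groups and the MAE; when `FALSE` all region members do.
#' @return a list of class `cluster_config`.
#' @export
cluster_config <- function(p_threshold = 0.05, max_gap_bp = 5000,
                           min_significant = 10, r2_threshold = 0.4,
                           mae_threshold = 3.0, log_base = 10,
                           min_group_size = 2, significant_only_mae = TRUE) {
  stopifnot(p_threshold > 0, p_threshold < 1, max_gap_bp > 0,
            min_significant > 0, r2_threshold > 0, r2_threshold < 1,
            mae_threshold > 0, log_base > 1, min_group_size >= 1)
  structure(list(p_threshold = p_threshold, max_gap_bp = max_gap_bp,
                 min_significant = min_significant,
                 r2_threshold = r2_threshold, mae_threshold = mae_threshold,
                 log_base = log_base, min_group_size = min_group_size,
                 significant_only_mae = significant_only_mae),
            class = "cluster_config")
}

#' Chain significant SNPs into genomic regions
#'
#' Per chromosome, SNPs with p below `p_threshold` are single-linkage
#' chained: consecutive significant SNPs no more than `max_gap_bp` apart
#' join the same region. Chains with fewer than `min_significant`
#' significant SNPs are discarded. Region boundaries are the min/max
#' positions of the chain's significant SNPs; `all_snps` then collects every
#' input SNP (significant or not) inside the boundaries. Non-significant
#' SNPs neither bridge nor break chains.
#'
#' @param assoc association `data.frame` (see [read_assoc()]), sorted by
#'   (chrom, bp).
#' @param config a [cluster_config()].
#' @return list of unscored region objects (class `snp_region`), each with
#'   elements `chrom`, `start_bp`, `end_bp`, `significant_snps`, `all_snps`,
#'   `signal_groups` (empty), `prioritized` (`NA`).
#' @export
chain_regions <- function(assoc, config = cluster_config()) {
  if (nrow(assoc) == 0L) return(list())
  k <- chrom_order_key(assoc$chrom)
  if (any(order(k[[1]], k[[2]], assoc$bp) != seq_len(nrow(assoc))))
    stop("association records must be sorted by (chrom, bp); use read_assoc()")
  regions <- list()
  for (chrom in unique(assoc$chrom)) {
    on_chr <- assoc[assoc$chrom == chrom, , drop = FALSE]
    sig <- on_chr[on_chr$p_value < config$p_threshold, , drop = FALSE]
    if (nrow(sig) == 0L) next
    gap <- diff(sig$bp)
    chain_id <- cumsum(c(1L, as.integer(gap > config$max_gap_bp)))
    for (id in unique(chain_id)) {
      members <- sig[chain_id == id, , drop = FALSE]
      if (nrow(members) < config$min_significant) next
      start_bp <- min(members$bp); end_bp <- max(members$bp)
      all_snps <- on_chr[on_chr$bp >= start_bp & on_chr$bp <= end_bp, ,
                         drop = FALSE]
      rownames(members) <- rownames(all_snps) <- NULL
      regions[[length(regions) + 1L]] <- structure(
        list(chrom = chrom, start_bp = start_bp, end_bp = end_bp,
             significant_snps = members, all_snps = all_snps,
             signal_groups = list(), prioritized = NA),
        class = "snp_region")
    }
  }
  regions
}

#' Predicted -log10 p from LD to the top SNP
#'
#' The consistency model: a SNP in LD r^2 with the group's top SNP is
#' expected to show `s_hat = s_max * r^2`, where `s_max` is the top SNP's
#' -log10 p. The no-LD-information sentinel propagates.
#'
#' @param s_max -log10 p of the top SNP (non-negative).
#' @param r2 LD between the member and the top SNP, in \[0, 1\].
#' @return predicted -log10 p (vectorized).
#' @export
predicted_neglogp <- function(s_max, r2) s_max * r2

#' Mean absolute error of a signal group
#'
#' `MAE = sum_k |s_k - s_hat_k| / K` over the K group members, where
#' `s_hat_k = s_max * r2_k` and `s_max = max(s)`. The top SNP (r^2 = 1)
#' contributes a zero residual and is included in the average. Any
#' no-LD-information r^2 makes the whole group unscoreable (sentinel MAE).
#'
#' @param s numeric vector of member -log10 p-values (finite, >= 0).
#' @param r2 numeric vector of member r^2 to the top SNP, same length.
#' @return the MAE, or the no-LD-information sentinel.
#' @export
group_mae <- function(s, r2) {
  if (length(s) == 0L) stop("empty signal group")
  if (length(s) != length(r2)) stop("s and r2 differ in length")
  if (any(!is.finite(s)) || any(s < 0)) stop("s values must be finite and >= 0")
  if (any(is_no_ld_info(r2))) return(NO_LD_INFO)
  s_max <- max(s)
  mean(abs(s - predicted_neglogp(s_max, r2)))
}

#' Form and score signal groups within a region
#'
#' Within each effect direction (OR > 1 / OR < 1), signal groups are formed
#' by iterative greedy re-anchoring: the unassigned significant SNP with the
#' largest -log10 p becomes a top SNP, every unassigned same-direction
#' significant SNP with r^2 to it above `r2_threshold` joins its group
#' (including the top itself), and the procedure repeats until every
#' significant SNP of that direction is assigned. Ties on -log10 p break by
#' smaller position, then lexicographic snp_id. SNPs with OR exactly 1
#' (direction NEUTRAL) are reported in the region but never grouped or
#' scored. Each group's predicted values, residuals and MAE come from
#' [predicted_neglogp()] and [group_mae()]; groups whose top SNP lacks LD
#' information, and groups smaller than `min_group_size`, carry the
#' sentinel MAE and cannot prioritize a region.
#'
#' @param region an unscored region from [chain_regions()].
#' @param ld_source a [genotype_table()] covering the region's SNPs, or an
#'   `ld_table` from [read_plink_ld()].
#' @param config a [cluster_config()].
#' @return the region with `signal_groups` populated; each group has
#'   `direction`, `top_snp`, `members` (data.frame), `r2`, `predicted`,
#'   `residuals`, `mae`.
#' @export
form_signal_groups <- function(region, ld_source, config = cluster_config()) {
  lookup <- ld_lookup(ld_source)
  pool <- if (isTRUE(config$significant_only_mae)) region$significant_snps
          else region$all_snps
  pool$direction <- or_direction(pool$odds_ratio)
  groups <- list()
  for (dir in c("UP", "DOWN")) {
    cand <- pool[pool$direction == dir, , drop = FALSE]
    while (nrow(cand) > 0L) {
      ord <- order(-cand$neg_log_p, cand$bp, cand$snp_id)
      cand <- cand[ord, , drop = FALSE]
      top <- cand[1L, , drop = FALSE]
      r2 <- lookup(top$snp_id, cand$snp_id)
      take <- rep(FALSE, nrow(cand))
      take[1L] <- TRUE
      known <- !is_no_ld_info(r2)
      take[known & r2 > config$r2_threshold] <- TRUE
      members <- cand[take, , drop = FALSE]
      m_r2 <- r2[take]
      s <- members$neg_log_p
      if (any(is_no_ld_info(m_r2)) || nrow(members) < config$min_group_size) {
        predicted <- rep(NA_real_, nrow(members))
        residuals <- rep(NA_real_, nrow(members))
        mae <- NO_LD_INFO
      } else {
        predicted <- predicted_neglogp(max(s), m_r2)
        residuals <- abs(s - predicted)
        mae <- group_mae(s, m_r2)
      }
      rownames(members) <- NULL
      groups[[length(groups) + 1L]] <- list(
        direction = dir, top_snp = top, members = members, r2 = m_r2,
        predicted = predicted, residuals = residuals, mae = mae)
      cand <- cand[!take, , drop = FALSE]
    }
  }
  region$signal_groups <- groups
  region
}

#' Flag prioritized regions
#'
#' A region is prioritized when at least one of its signal groups has a
#' non-sentinel MAE strictly below `mae_threshold`. A group MAE of exactly
#' 3.0 does not prioritize under the default threshold.
#'
#' @param regions list of scored regions.
#' @param config a [cluster_config()].
#' @return the regions with `prioritized` set.
#' @export
prioritize <- function(regions, config = cluster_config()) {
  lapply(regions, function(rg) {
    maes <- vapply(rg$signal_groups, function(g) g$mae, numeric(1))
    rg$prioritized <- any(vapply(maes, function(m)
      isTRUE(m < config$mae_threshold), logical(1)))
    rg
  })
}

#' Run the full LD-consistency prioritization
#'
#' Composition of [chain_regions()], [form_signal_groups()] and
#' [prioritize()]: chains significant SNPs into regions, scores the LD /
#' p-value consistency of each direction signal group by MAE, flags
#' prioritized regions, and collects the summary statistics of all SNPs
#' inside prioritized region boundaries.
#'
#' @param assoc association `data.frame` sorted by (chrom, bp), as returned
#'   by [read_assoc()] or [logistic_assoc_additive()].
#' @param ld_source a [genotype_table()] or an `ld_table` from
#'   [read_plink_ld()].
#' @param config a [cluster_config()].
#' @return an object of class `cluster_scan`: a list with `regions` (scored
#'   region list), `prioritized_assoc` (data.frame of SNPs inside
#'   prioritized regions), `assoc` (the input), `config`, and `counts`
#'   (n_snps, n_regions, n_prioritized_regions, n_prioritized_snps).
#' @seealso [summary.cluster_scan()], [plot.cluster_scan()],
#'   [residuals.cluster_scan()]
#' @export
run_cluster_analyzer <- function(assoc, ld_source,
                                 config = cluster_config()) {
  regions <- chain_regions(assoc, config)
  regions <- lapply(regions, form_signal_groups, ld_source = ld_source,
                    config = config)
  regions <- prioritize(regions, config)
  keep <- rep(FALSE, nrow(assoc))
  for (rg in regions) {
    if (!isTRUE(rg$prioritized)) next
    keep <- keep | (assoc$chrom == rg$chrom & assoc$bp >= rg$start_bp &
                    assoc$bp <= rg$end_bp)
  }
  pri <- assoc[keep, , drop = FALSE]
  rownames(pri) <- NULL
  structure(list(
    regions = regions,
    prioritized_assoc = pri,
    assoc = assoc,
    config = config,
    counts = list(
      n_snps = nrow(assoc),
      n_regions = length(regions),
      n_prioritized_regions = sum(vapply(regions, function(r)
        isTRUE(r$prioritized), logical(1))),
      n_prioritized_snps = nrow(pri))
  ), class = "cluster_scan")
}
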