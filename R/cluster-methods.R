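#' @export
print.cluster_config <- function(x, ...) {
  cat("cluster_config:\n")
  cat(sprintf("  significance: p < %g\n", x$p_threshold))
  cat(sprintf("  chaining gap: <= %d bp between significant SNPs\n",
              as.integer(x$max_gap_bp)))
  cat(sprintf("  region size : >= %d significant SNPs\n",
              as.integer(x$min_significant)))
  cat(sprintf("  LD grouping : r^2 > %g to the top SNP\n", x$r2_threshold))
  cat(sprintf("  prioritize  : some group MAE < %g (group size >= %d)\n",
              x$mae_threshold, as.integer(x$min_group_size)))
  invisible(x)
}

#' @export
print.snp_region <- function(x, ...) {
  cat(sprintf("region %s:%d-%d  %d significant / %d total SNPs, %d group(s)%s\n",
              x$chrom, x$start_bp, x$end_bp, nrow(x$significant_snps),
              nrow(x$all_snps), length(x$signal_groups),
              if (isTRUE(x$prioritized)) "  [prioritized]" else ""))
  invisible(x)
}

#' @export
print.cluster_scan <- function(x, ...) {
  cat("LD-consistency prioritization scan\n")
  cat(sprintf("  %d SNPs -> %d region(s), %d prioritized containing %d SNP(s)\n",
              x$counts$n_snps, x$counts$n_regions,
              x$counts$n_prioritized_regions, x$counts$n_prioritized_snps))
  invisible(x)
}

#' Region-level summary of a prioritization scan
#'
#' @param object a `cluster_scan` from [run_cluster_analyzer()].
#' @param ... unused.
#' @return the [region_table()] data frame, with the scan counts attached as
#'   attribute `counts`.
#' @export
summary.cluster_scan <- function(object, ...) {
  tab <- region_table(object$regions)
  attr(tab, "counts") <- object$counts
  class(tab) <- c("summary.cluster_scan", class(tab))
  tab
}

#' @export
print.summary.cluster_scan <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat(sprintf("%d region(s) from %d SNPs; %d prioritized (%d SNPs)\n\n",
              cnt$n_regions, cnt$n_snps, cnt$n_prioritized_regions,
              cnt$n_prioritized_snps))
  print.data.frame(x)
  invisible(x)
}

#' Per-SNP consistency residuals of a scan
#'
#' Residuals `|s - s_max * r^2|` of every scored signal-group member, the
#' quantity averaged into each group's MAE.
#'
#' @param object a `cluster_scan`.
#' @param ... unused.
#' @return `data.frame` with columns `region` (chrom:start-end), `direction`,
#'   `top_snp_id`, `snp_id`, `neg_log_p`, `r2`, `predicted`, `residual`.
#' @export
residuals.cluster_scan <- function(object, ...) {
  rows <- list()
  for (rg in object$regions) {
    rid <- sprintf("%s:%d-%d", rg$chrom, rg$start_bp, rg$end_bp)
    for (g in rg$signal_groups) {
      rows[[length(rows) + 1L]] <- data.frame(
        region = rid, direction = g$direction,
        top_snp_id = g$top_snp$snp_id, snp_id = g$members$snp_id,
        neg_log_p = g$members$neg_log_p, r2 = g$r2,
        predicted = g$predicted, residual = g$residuals,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(region = character(), direction = character(),
                      top_snp_id = character(), snp_id = character(),
                      neg_log_p = numeric(), r2 = numeric(),
                      predicted = numeric(), residual = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Manhattan plot of a scan
#'
#' Plots all tested SNPs at cumulative genome coordinates (grey), overlays
#' SNPs inside prioritized regions (color), and draws the conventional
#' guide lines at p = 1e-5 and p = 5e-8.
#'
#' @param x a `cluster_scan`.
#' @param highlight_col color for SNPs in prioritized regions.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the Manhattan coordinate data frame.
#' @export
plot.cluster_scan <- function(x, highlight_col = "firebrick", ...) {
  pd <- plot_data(x$assoc)
  man <- pd$manhattan
  graphics::plot(man$cum_bp, man$neg_log_p, pch = 20, cex = 0.5,
                 col = "grey55", xlab = "cumulative position (bp)",
                 ylab = expression(-log[10](p)), ...)
  key <- paste(x$assoc$chrom, x$assoc$bp)
  pri <- paste(x$prioritized_assoc$chrom, x$prioritized_assoc$bp)
  hit <- key %in% pri
  if (any(hit))
    graphics::points(man$cum_bp[hit], man$neg_log_p[hit], pch = 20,
                     cex = 0.6, col = highlight_col)
  graphics::abline(h = -log10(1e-5), col = "red", lty = 2)
  graphics::abline(h = -log10(5e-8), col = "darkgreen", lty = 2)
  invisible(man)
}
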