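#' Genomic inflation factor (lambda GC)
#'
#' The median association chi-square statistic (1 df, recovered from the
#' p-values via the upper-tail quantile function) divided by the median of
#' the null chi-square(1) distribution. Lambda is 1 under a well-calibrated
#' null; values above 1 indicate inflation -- either confounding or, as when
#' a scan is restricted to prioritized signal-dense regions, genuine
#' enrichment of association.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return lambda (positive scalar).
#' @export
genomic_inflation <- function(p_values) {
  if (length(p_values) == 0L) stop("empty p-value vector")
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  chisq <- qchisq(p_values, df = 1, lower.tail = FALSE)
  median(chisq) / qchisq(0.5, df = 1)
}

#' Manhattan and QQ plot coordinates
#'
#' Computes deterministic plotting coordinates from an association table:
#' Manhattan x-positions as cumulative base-pair offsets (each chromosome
#' placed after the previous chromosome's largest position) against
#' -log10 p, and QQ coordinates of observed versus expected -log10 p with
#' `expected_i = -log10((i - 0.5) / n)` for ascending rank i.
#'
#' @param assoc association `data.frame` (see [read_assoc()]).
#' @return list with `manhattan` (`chrom`, `bp`, `cum_bp`, `neg_log_p`),
#'   `qq` (`expected`, `observed`, sorted ascending), and `guide_lines`
#'   (suggestive 1e-5 and genome-wide 5e-8 levels on the -log10 scale).
#' @export
plot_data <- function(assoc) {
  if (nrow(assoc) == 0L) stop("empty association table")
  assoc <- sort_by_locus(assoc)
  chroms <- unique(assoc$chrom)
  offset <- 0
  cum <- numeric(nrow(assoc))
  for (ch in chroms) {
    i <- assoc$chrom == ch
    cum[i] <- assoc$bp[i] + offset
    offset <- offset + max(assoc$bp[i])
  }
  obs <- sort(assoc$neg_log_p)                     # ascending observed
  nq <- length(obs)
  expected <- -log10((seq_len(nq) - 0.5) / nq)     # descending
  qq <- data.frame(expected = rev(expected), observed = obs)
  qq <- qq[order(qq$expected), , drop = FALSE]
  rownames(qq) <- NULL
  list(
    manhattan = data.frame(chrom = assoc$chrom, bp = assoc$bp,
                           cum_bp = cum, neg_log_p = assoc$neg_log_p,
                           stringsAsFactors = FALSE),
    qq = qq,
    guide_lines = c(suggestive = -log10(1e-5), genome_wide = -log10(5e-8))
  )
}
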