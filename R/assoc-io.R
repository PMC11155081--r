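#' Read association summary statistics (PLINK logistic dialect)
#'
#' Reads a whitespace-delimited summary-statistic table with a header line,
#' the layout written by PLINK's logistic association test
#' (`CHR SNP BP A1 TEST NMISS OR STAT P`). Only the columns CHR, BP, A1, OR
#' and P are required (SNP is optional and defaults to "."). When a TEST
#' column is present only rows with `TEST == "ADD"` (the additive dosage
#' term) are kept; covariate rows are excluded. Rows whose OR or P field is
#' `NA` are dropped, with a message giving the count.
#'
#' Chromosome labels are normalized by stripping a leading `"chr"`.
#' Non-autosomal records (CHR not in 1..22) are excluded by default. The
#' result is sorted by (chromosome, position) and carries a `neg_log_p`
#' column equal to `-log10(p_value)`.
#'
#' @param path path to the summary-statistic file.
#' @param p_column,or_column,bp_column optional column-name overrides for
#'   the P, OR and BP columns.
#' @param autosomes_only drop non-autosomal records (default `TRUE`).
#' @return a `data.frame` with columns `chrom`, `bp`, `snp_id`, `a1`,
#'   `odds_ratio`, `p_value`, `neg_log_p`, sorted by (chrom, bp). The number
#'   of rows dropped for missing OR/P is attached as attribute `n_dropped_na`.
#' @export
read_assoc <- function(path, p_column = "P", or_column = "OR",
                       bp_column = "BP", autosomes_only = TRUE) {
  if (!file.exists(path)) stop("association file not found: ", path)
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = "NA")
  required <- c("CHR", bp_column, "A1", or_column, p_column)
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L)
    stop("association file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if ("TEST" %in% names(tab)) {
    n_other <- sum(tab$TEST != "ADD")
    if (n_other > 0L)
      message("read_assoc: excluding ", n_other, " non-ADD test row(s)")
    tab <- tab[tab$TEST == "ADD", , drop = FALSE]
  }
  or <- suppressWarnings(as.numeric(tab[[or_column]]))
  pv <- suppressWarnings(as.numeric(tab[[p_column]]))
  bad_num <- (!is.na(tab[[or_column]]) & is.na(or)) |
             (!is.na(tab[[p_column]]) & is.na(pv))
  if (any(bad_num))
    stop("unparsable OR/P value at data row(s): ",
         paste(head(which(bad_num), 5L), collapse = ", "))
  drop <- is.na(or) | is.na(pv)
  n_dropped <- sum(drop)
  if (n_dropped > 0L)
    message("read_assoc: dropped ", n_dropped, " row(s) with NA OR/P")
  tab <- tab[!drop, , drop = FALSE]
  or <- or[!drop]; pv <- pv[!drop]

  bp <- suppressWarnings(as.integer(tab[[bp_column]]))
  if (any(is.na(bp)))
    stop("unparsable BP value at data row(s): ",
         paste(head(which(is.na(bp)), 5L), collapse = ", "))
  out <- data.frame(
    chrom = norm_chrom(tab$CHR),
    bp = bp,
    snp_id = if ("SNP" %in% names(tab)) as.character(tab$SNP) else
      rep(".", nrow(tab)),
    a1 = as.character(tab$A1),
    odds_ratio = or,
    p_value = pv,
    stringsAsFactors = FALSE
  )
  out <- validate_assoc(out)
  if (autosomes_only) {
    n_allo <- sum(!(out$chrom %in% AUTOSOMES))
    if (n_allo > 0L)
      message("read_assoc: excluding ", n_allo, " non-autosomal record(s)")
    out <- out[out$chrom %in% AUTOSOMES, , drop = FALSE]
  }
  out$neg_log_p <- -log10(out$p_value)
  out <- sort_by_locus(out)
  rownames(out) <- NULL
  attr(out, "n_dropped_na") <- n_dropped
  out
}

# internal: check field invariants of an association table
validate_assoc <- function(df) {
  if (nrow(df) == 0L) return(df)
  if (any(df$bp < 1L)) stop("positions must be >= 1")
  if (any(df$odds_ratio <= 0)) stop("odds ratios must be positive")
  if (any(df$p_value <= 0 | df$p_value > 1)) stop("p-values must lie in (0, 1]")
  df
}

#' Effect-direction classification from an odds ratio
#'
#' `"UP"` for OR > 1, `"DOWN"` for OR < 1, `"NEUTRAL"` for OR exactly 1.
#' NEUTRAL SNPs cannot anchor or join a direction signal group.
#'
#' @param odds_ratio numeric vector of odds ratios.
#' @return character vector of direction labels.
#' @export
or_direction <- function(odds_ratio) {
  ifelse(odds_ratio > 1, "UP", ifelse(odds_ratio < 1, "DOWN", "NEUTRAL"))
}

#' Write association records in the PLINK dialect
#'
#' Writes a whitespace-aligned table with header `CHR SNP BP A1 OR P`.
#' Odds ratios and p-values are printed at full double precision so that
#' [read_assoc()] on the output reproduces the input records exactly.
#'
#' @param assoc association `data.frame` as returned by [read_assoc()].
#' @param path output path.
#' @return invisibly, the output path.
#' @export
write_assoc <- function(assoc, path) {
  cols <- data.frame(
    CHR = as.character(assoc$chrom),
    SNP = assoc$snp_id,
    BP = format(assoc$bp, scientific = FALSE, trim = TRUE),
    A1 = assoc$a1,
    OR = sprintf("%.17g", assoc$odds_ratio),
    P = sprintf("%.17g", assoc$p_value),
    stringsAsFactors = FALSE
  )
  widths <- pmax(nchar(names(cols)), sapply(cols, function(x) max(0L, nchar(x))))
  fmt_row <- function(vals) paste(mapply(formatC, vals, width = widths,
                                         MoreArgs = list(flag = "-")),
                                  collapse = " ")
  lines <- c(fmt_row(names(cols)),
             if (nrow(cols) > 0L) apply(cols, 1L, fmt_row))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(trimws(lines, which = "right"), con)
  invisible(path)
}

#' Write summary statistics of SNPs inside prioritized regions
#'
#' Restricts an association table to SNPs falling inside the boundaries of
#' prioritized regions and writes them in the PLINK dialect of
#' [write_assoc()]. With no prioritized regions a header-only file is
#' written.
#'
#' @param assoc association `data.frame`.
#' @param regions list of region objects (see [chain_regions()]), or a
#'   `cluster_scan` object.
#' @param path output path.
#' @return invisibly, the output path.
#' @export
write_prioritized_assoc <- function(assoc, regions, path) {
  if (inherits(regions, "cluster_scan")) regions <- regions$regions
  keep <- rep(FALSE, nrow(assoc))
  for (rg in regions) {
    if (!isTRUE(rg$prioritized)) next
    keep <- keep | (assoc$chrom == rg$chrom &
                    assoc$bp >= rg$start_bp & assoc$bp <= rg$end_bp)
  }
  write_assoc(assoc[keep, , drop = FALSE], path)
}
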