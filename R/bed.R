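#' Read gene intervals from a BED4 file
#'
#' BED coordinates are 0-based, half-open; they are kept in that convention
#' here and converted to 1-based inclusive only inside [annotate_regions()].
#' At least four tab-separated columns (chrom, start, end, name) are
#' required; rows with `start >= end` are an error.
#'
#' @param path path to a BED file (no header).
#' @return `data.frame` with columns `chrom` (normalized, "chr" stripped),
#'   `start`, `end`, `gene_name`, sorted by (chrom, start).
#' @export
read_bed_genes <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), gene_name = character(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 4L)
  if (length(short) > 0L)
    stop("BED row ", short[1L], " has fewer than 4 columns (name required)")
  df <- data.frame(
    chrom = norm_chrom(vapply(fields, `[`, "", 1L)),
    start = as.integer(vapply(fields, `[`, "", 2L)),
    end = as.integer(vapply(fields, `[`, "", 3L)),
    gene_name = vapply(fields, `[`, "", 4L),
    stringsAsFactors = FALSE
  )
  if (any(is.na(df$start) | is.na(df$end)))
    stop("unparsable BED coordinates at row ",
         which(is.na(df$start) | is.na(df$end))[1L])
  bad <- which(df$start >= df$end)
  if (length(bad) > 0L)
    stop("BED row ", bad[1L], ": start >= end")
  k <- chrom_order_key(df$chrom)
  df <- df[order(k[[1]], k[[2]], df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Summarize regions as a data frame
#'
#' One row per region: boundaries, SNP counts, number of signal groups, best
#' (smallest) non-sentinel group MAE, the overall top SNP, and the
#' prioritization flag. This is the table written by [write_region_tsv()].
#'
#' @param regions list of region objects or a `cluster_scan`.
#' @return `data.frame` ordered by (chrom, start_bp).
#' @export
region_table <- function(regions) {
  if (inherits(regions, "cluster_scan")) regions <- regions$regions
  if (length(regions) == 0L)
    return(data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), n_snps_total = integer(),
                      n_snps_significant = integer(),
                      n_signal_groups = integer(), best_mae = numeric(),
                      top_snp_id = character(), top_snp_p = numeric(),
                      prioritized = logical(), stringsAsFactors = FALSE))
  rows <- lapply(regions, function(rg) {
    maes <- vapply(rg$signal_groups, function(g) g$mae, numeric(1))
    scoreable <- maes[!is_no_ld_info(maes)]
    top <- rg$significant_snps[which.max(rg$significant_snps$neg_log_p), ]
    data.frame(
      chrom = rg$chrom, start_bp = rg$start_bp, end_bp = rg$end_bp,
      n_snps_total = nrow(rg$all_snps),
      n_snps_significant = nrow(rg$significant_snps),
      n_signal_groups = length(rg$signal_groups),
      best_mae = if (length(scoreable)) min(scoreable) else NA_real_,
      top_snp_id = top$snp_id, top_snp_p = top$p_value,
      prioritized = isTRUE(rg$prioritized),
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  k <- chrom_order_key(df$chrom)
  df <- df[order(k[[1]], k[[2]], df$start_bp), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write the region summary as TSV
#'
#' Tab-delimited, one header row, one row per region, ordered by
#' (chromosome, start position). The column layout (see [region_table()])
#' is this package's reconstruction of a region report; it is not a
#' standardized format.
#'
#' @param regions list of region objects or a `cluster_scan`.
#' @param path output path.
#' @return invisibly, the output path.
#' @export
write_region_tsv <- function(regions, path) {
  df <- region_table(regions)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
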