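#' Map prioritized regions to overlapping genes
#'
#' Each prioritized region is extended by `flank_bp` on both ends (floored
#' at position 1) and intersected with gene intervals; any overlap of at
#' least 1 bp counts (no nearest-gene fallback). Region coordinates are
#' 1-based inclusive, BED gene intervals 0-based half-open; the conversion
#' happens here and nowhere else. Chromosome labels are compared after
#' normalization ("chr" prefix stripped).
#'
#' @param regions list of region objects, a `cluster_scan`, or a
#'   [region_table()]-layout data.frame; only prioritized regions are
#'   annotated.
#' @param genes gene intervals from [read_bed_genes()].
#' @param flank_bp extension on each end, in bp (default 5000).
#' @return list with `hits` (`data.frame`: `region` as chrom:start-end of
#'   the unflanked region, `gene_name`, `overlap_bp`) and `genes` (unique,
#'   sorted gene names).
#' @export
annotate_regions <- function(regions, genes, flank_bp = 5000) {
  if (inherits(regions, "cluster_scan")) regions <- regions$regions
  if (is.data.frame(regions)) {
    rdf <- regions[isTRUE_vec(regions$prioritized), , drop = FALSE]
  } else {
    keep <- vapply(regions, function(r) isTRUE(r$prioritized), logical(1))
    rdf <- do.call(rbind, lapply(regions[keep], function(r)
      data.frame(chrom = r$chrom, start_bp = r$start_bp, end_bp = r$end_bp,
                 stringsAsFactors = FALSE)))
  }
  empty <- list(hits = data.frame(region = character(),
                                  gene_name = character(),
                                  overlap_bp = integer(),
                                  stringsAsFactors = FALSE),
                genes = character())
  if (is.null(rdf) || nrow(rdf) == 0L || nrow(genes) == 0L) return(empty)

  rid <- sprintf("%s:%d-%d", norm_chrom(rdf$chrom),
                 as.integer(rdf$start_bp), as.integer(rdf$end_bp))
  rgr <- GenomicRanges::GRanges(
    seqnames = norm_chrom(rdf$chrom),
    ranges = IRanges::IRanges(
      start = pmax(1L, as.integer(rdf$start_bp) - as.integer(flank_bp)),
      end = as.integer(rdf$end_bp) + as.integer(flank_bp)))
  # BED 0-based half-open -> 1-based inclusive
  ggr <- GenomicRanges::GRanges(
    seqnames = norm_chrom(genes$chrom),
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end))
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(rgr, ggr, minoverlap = 1L))
  if (length(ov) == 0L) return(empty)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  width <- GenomicRanges::width(
    IRanges::pintersect(IRanges::ranges(rgr)[qi], IRanges::ranges(ggr)[si]))
  hits <- data.frame(region = rid[qi], gene_name = genes$gene_name[si],
                     overlap_bp = as.integer(width), stringsAsFactors = FALSE)
  hits <- hits[order(hits$region, hits$gene_name), , drop = FALSE]
  rownames(hits) <- NULL
  list(hits = hits, genes = sort(unique(hits$gene_name)))
}

# internal: vectorized isTRUE for logical columns that may hold NA
isTRUE_vec <- function(x) !is.na(x) & x
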