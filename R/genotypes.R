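#' Construct a genotype table
#'
#' A genotype table holds additive alt-allele dosages (0/1/2, `NA` for
#' missing) for samples x variants together with variant metadata. Variants
#' are stored sorted by (chromosome, position); duplicated
#' (chrom, bp, ref, alt) tuples are rejected.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns;
#'   entries must be 0, 1, 2 or `NA`.
#' @param variants `data.frame` with columns `chrom`, `bp`, `snp_id`, `ref`,
#'   `alt` (one row per dosage column).
#' @param sample_ids character vector of sample identifiers (one per row).
#' @return an object of class `genotype_table` with elements `dosages`,
#'   `variants`, `sample_ids`.
#' @export
genotype_table <- function(dosages, variants, sample_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosages)))
  stopifnot(nrow(variants) == ncol(dosages),
            length(sample_ids) == nrow(dosages))
  vals <- dosages[!is.na(dosages)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stop("dosages must be 0, 1, 2 or NA")
  variants$chrom <- norm_chrom(variants$chrom)
  variants$bp <- as.integer(variants$bp)
  key <- paste(variants$chrom, variants$bp, variants$ref, variants$alt)
  if (anyDuplicated(key))
    stop("duplicated variant (chrom, bp, alleles) tuples are not allowed")
  ord <- {
    k <- chrom_order_key(variants$chrom)
    order(k[[1]], k[[2]], variants$bp)
  }
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  dosages <- dosages[, ord, drop = FALSE]
  dimnames(dosages) <- list(sample_ids, variants$snp_id)
  structure(list(dosages = dosages, variants = variants,
                 sample_ids = sample_ids),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$sample_ids), "samples x",
      nrow(x$variants), "variants\n")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missingness: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$dosages)

#' Subset a genotype table
#'
#' @param x a `genotype_table`.
#' @param samples sample index (integer/logical/character).
#' @param variants variant index (integer/logical/character snp_id).
#' @return a `genotype_table`.
#' @export
subset_genotypes <- function(x, samples = NULL, variants = NULL) {
  d <- x$dosages; v <- x$variants; s <- x$sample_ids
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, s)
    d <- d[samples, , drop = FALSE]; s <- s[samples]
  }
  if (!is.null(variants)) {
    if (is.character(variants)) variants <- match(variants, v$snp_id)
    d <- d[, variants, drop = FALSE]; v <- v[variants, , drop = FALSE]
  }
  rownames(v) <- NULL
  structure(list(dosages = d, variants = v, sample_ids = s),
            class = "genotype_table")
}

#' Read genotypes from a VCF file
#'
#' Converts biallelic single-nucleotide variants to additive alt-allele
#' dosages. Multi-allelic sites and non-SNVs (indels, MNVs) are skipped with
#' a message; their counts are attached as attributes `n_multiallelic` and
#' `n_nonsnv`. Missing genotypes (`./.` or `.`) become missing dosages;
#' phasing is ignored.
#'
#' @param path path to a VCF (plain or bgzipped).
#' @return a [genotype_table()].
#' @export
read_genotypes_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("VCF contains no variant records: ", path)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  snv <- !multi & nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_multi <- sum(multi)
  n_nonsnv <- sum(!multi & !snv)
  if (n_multi > 0L)
    message("read_genotypes_vcf: skipping ", n_multi, " multi-allelic site(s)")
  if (n_nonsnv > 0L)
    message("read_genotypes_vcf: skipping ", n_nonsnv, " non-SNV site(s)")
  keep <- which(snv)
  if (length(keep) == 0L) stop("no biallelic SNVs in VCF: ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  # count "1" alleles in the GT string; any "." allele -> missing
  dose_of <- function(g) {
    if (is.na(g)) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles == "1")
  }
  dosages <- t(apply(gt, c(1L, 2L), dose_of))
  ids <- fix$ID[keep]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix$CHROM[keep], ":", fix$POS[keep])[is.na(ids) | ids == "."]
  variants <- data.frame(
    chrom = fix$CHROM[keep], bp = as.integer(fix$POS[keep]), snp_id = ids,
    ref = fix$REF[keep], alt = fix$ALT[keep], stringsAsFactors = FALSE
  )
  out <- genotype_table(dosages, variants, sample_ids = colnames(gt))
  attr(out, "n_multiallelic") <- n_multi
  attr(out, "n_nonsnv") <- n_nonsnv
  out
}

#' Read genotypes from a plain dosage table
#'
#' Tab-delimited dialect used for desk-scale runs and by the simulator:
#' first column `sample_id`, one further column per variant whose header
#' encodes the locus as `chrom:bp:snp_id[:ref:alt]`, and cells in
#' \{0, 1, 2, NA\}.
#'
#' @param path path to the dosage table.
#' @return a [genotype_table()].
#' @seealso [write_genotypes_table()]
#' @export
read_genotypes_table <- function(path) {
  if (!file.exists(path)) stop("dosage table not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = "NA",
                    colClasses = "character")
  if (ncol(tab) < 2L) stop("dosage table needs a sample_id column plus variants")
  sample_ids <- tab[[1L]]
  vcols <- names(tab)[-1L]
  d <- suppressWarnings(vapply(tab[-1L], as.numeric, numeric(nrow(tab))))
  d <- matrix(d, nrow = nrow(tab),
              dimnames = list(sample_ids, vcols))
  bad_parse <- is.na(d) & !is.na(as.matrix(tab[-1L]))
  if (any(bad_parse))
    stop("unparsable dosage cell(s), e.g. row ",
         which(rowSums(bad_parse) > 0)[1L])
  vals <- d[!is.na(d)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stop("dosage out of range {0,1,2}: found ",
         paste(unique(vals[!vals %in% c(0, 1, 2)])[1:3], collapse = ", "))
  parts <- strsplit(vcols, ":", fixed = TRUE)
  nparts <- lengths(parts)
  if (any(nparts < 3L))
    stop("variant headers must be chrom:bp:snp_id[:ref:alt]")
  variants <- data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    bp = as.integer(vapply(parts, `[`, "", 2L)),
    snp_id = vapply(parts, `[`, "", 3L),
    ref = ifelse(nparts >= 5L, vapply(parts, `[`, "", 4L), "A"),
    alt = ifelse(nparts >= 5L, vapply(parts, `[`, "", 5L), "C"),
    stringsAsFactors = FALSE
  )
  genotype_table(d, variants, sample_ids = sample_ids)
}

#' Write a genotype table in the plain dosage dialect
#'
#' @param table a [genotype_table()].
#' @param path output path.
#' @return invisibly, the output path.
#' @export
write_genotypes_table <- function(table, path) {
  v <- table$variants
  headers <- paste(v$chrom, v$bp, v$snp_id, v$ref, v$alt, sep = ":")
  out <- data.frame(sample_id = table$sample_ids, stringsAsFactors = FALSE)
  d <- table$dosages
  storage.mode(d) <- "integer"
  out <- cbind(out, as.data.frame(d))
  names(out) <- c("sample_id", headers)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
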