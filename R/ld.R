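#' Pairwise LD (r^2) between two dosage vectors
#'
#' r^2 is the squared Pearson correlation of unphased additive dosages over
#' pairwise-complete samples (the allele-count r^2 PLINK 1.9 reports by
#' default for unphased data, not the EM haplotype estimate). When either
#' vector has zero variance over the pairwise-complete samples, or fewer
#' than two such samples exist, there is no LD information and the sentinel
#' (see [is_no_ld_info()]) is returned -- deliberately distinct from an r^2
#' of 0. Values within 1e-12 above 1 (floating-point overshoot) are clamped
#' to 1.
#'
#' @param a,b numeric dosage vectors of equal length.
#' @return squared correlation in \[0, 1\], or the no-LD-information sentinel.
#' @export
r2_pair <- function(a, b) {
  if (length(a) != length(b)) stop("dosage vectors differ in length")
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2L) return(NO_LD_INFO)
  a <- a[ok]; b <- b[ok]
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 || vb == 0) return(NO_LD_INFO)
  r <- cor(a, b)
  r2 <- r * r
  if (r2 > 1 && r2 <= 1 + 1e-12) r2 <- 1
  r2
}

#' LD of region members to an anchor (top) SNP
#'
#' Computes r^2 between one anchor variant and each member variant from a
#' genotype table. The anchor itself gets r^2 = 1 when its dosage variance
#' is non-zero, the sentinel otherwise.
#'
#' @param table a [genotype_table()].
#' @param anchor_id snp_id of the anchor variant.
#' @param member_ids snp_ids of the member variants (may include the anchor).
#' @return `data.frame` with columns `top_snp_id`, `member_snp_id`, `r2`.
#' @export
r2_to_anchor <- function(table, anchor_id, member_ids) {
  ids <- table$variants$snp_id
  ai <- match(anchor_id, ids)
  if (is.na(ai)) stop("unknown anchor variant: ", anchor_id)
  mi <- match(member_ids, ids)
  if (anyNA(mi))
    stop("unknown member variant(s): ",
         paste(member_ids[is.na(mi)], collapse = ", "))
  av <- table$dosages[, ai]
  r2 <- vapply(mi, function(j) {
    if (j == ai) {
      if (sum(!is.na(av)) >= 2L && stats::var(av, na.rm = TRUE) > 0) 1
      else NO_LD_INFO
    } else r2_pair(av, table$dosages[, j])
  }, numeric(1))
  data.frame(top_snp_id = anchor_id, member_snp_id = member_ids, r2 = r2,
             stringsAsFactors = FALSE)
}

#' Read a precomputed LD table (PLINK .ld layout)
#'
#' Whitespace-delimited table with header columns
#' `CHR_A BP_A SNP_A CHR_B BP_B SNP_B R2`, as written by PLINK's `--r2`.
#' The result can stand in for genotypes as the LD source of
#' [run_cluster_analyzer()] and [form_signal_groups()].
#'
#' @param path path to the .ld file.
#' @return `data.frame` of class `ld_table` with columns `snp_a`, `snp_b`,
#'   `r2` (symmetric lookup is handled downstream).
#' @export
read_plink_ld <- function(path) {
  if (!file.exists(path)) stop("LD file not found: ", path)
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("SNP_A", "SNP_B", "R2")
  if (!all(need %in% names(tab)))
    stop("LD file missing column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  out <- data.frame(snp_a = as.character(tab$SNP_A),
                    snp_b = as.character(tab$SNP_B),
                    r2 = as.numeric(tab$R2), stringsAsFactors = FALSE)
  class(out) <- c("ld_table", class(out))
  out
}

# internal: turn a genotype table / ld_table into a lookup
# function(anchor_id, member_ids) -> numeric r2 vector
ld_lookup <- function(ld_source) {
  if (inherits(ld_source, "genotype_table")) {
    function(anchor_id, member_ids)
      r2_to_anchor(ld_source, anchor_id, member_ids)$r2
  } else if (inherits(ld_source, "ld_table")) {
    key <- c(paste(ld_source$snp_a, ld_source$snp_b),
             paste(ld_source$snp_b, ld_source$snp_a))
    val <- c(ld_source$r2, ld_source$r2)
    function(anchor_id, member_ids) {
      r2 <- val[match(paste(anchor_id, member_ids), key)]
      r2[member_ids == anchor_id] <- 1
      r2
    }
  } else {
    stop("LD source must be a genotype_table or an ld_table")
  }
}
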