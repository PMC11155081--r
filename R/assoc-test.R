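#' Covariate-adjusted additive logistic association
#'
#' Per variant, fits `logit P(case) = b0 + b1 * dosage + covariates` by
#' iteratively reweighted least squares (maximum 25 iterations, coefficient
#' convergence tolerance 1e-8) and reports the additive-model odds ratio
#' `exp(b1)` with its Wald p-value -- the model and test PLINK's `--logistic`
#' applies. Samples with a missing dosage are excluded per variant
#' (pairwise-complete). Variants whose fit does not converge or is
#' degenerate (complete separation, monomorphic dosage, unstable standard
#' error) are dropped; the count of dropped variants is reported in a
#' message and attached as attribute `n_failed`.
#'
#' @param table a [genotype_table()].
#' @param phenotype binary vector (1 = case, 0 = control), one per sample;
#'   both classes must be present.
#' @param covariates optional numeric matrix or data.frame of per-sample
#'   covariates (e.g. principal components, sex), full column rank.
#' @return association `data.frame` in the layout of [read_assoc()]
#'   (`chrom`, `bp`, `snp_id`, `a1`, `odds_ratio`, `p_value`, `neg_log_p`),
#'   sorted by (chrom, bp). The effect allele `a1` is the alt allele whose
#'   dosage is counted.
#' @export
logistic_assoc_additive <- function(table, phenotype, covariates = NULL) {
  y <- as.numeric(phenotype)
  if (length(y) != length(table$sample_ids))
    stop("phenotype length does not match sample count")
  if (!all(y %in% c(0, 1))) stop("phenotype must be binary 0/1")
  if (length(unique(y)) < 2L) stop("phenotype is constant; need both classes")
  n <- length(y)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    storage.mode(covariates) <- "double"
    if (nrow(covariates) != n) stop("covariate rows must match samples")
    if (qr(cbind(1, covariates))$rank < ncol(covariates) + 1L)
      stop("covariate matrix (with intercept) is rank deficient")
  }
  m <- nrow(table$variants)
  or <- rep(NA_real_, m); pv <- rep(NA_real_, m)
  ctrl <- list(epsilon = 1e-8, maxit = 25, trace = FALSE)
  for (j in seq_len(m)) {
    g <- table$dosages[, j]
    ok <- !is.na(g)
    if (sum(ok) < 3L) next
    gj <- g[ok]; yj <- y[ok]
    if (stats::var(gj) == 0 || length(unique(yj)) < 2L) next
    X <- cbind(`(Intercept)` = 1, dosage = gj,
               if (!is.null(covariates)) covariates[ok, , drop = FALSE])
    fit <- suppressWarnings(
      glm.fit(X, yj, family = binomial(), control = ctrl))
    if (!fit$converged || fit$boundary) next
    beta <- fit$coefficients["dosage"]
    if (!is.finite(beta)) next
    # Wald SE from the IRLS weighted cross-product
    w <- fit$weights
    XtWX <- crossprod(X * sqrt(w))
    cov_try <- try(solve(XtWX), silent = TRUE)
    if (inherits(cov_try, "try-error")) next
    se <- sqrt(cov_try["dosage", "dosage"])
    # separation / quasi-separation: explosive estimate or SE
    if (!is.finite(se) || se > 20 || abs(beta) > 15) next
    z <- beta / se
    or[j] <- exp(beta)
    pv[j] <- 2 * pnorm(-abs(z))
  }
  failed <- is.na(pv)
  if (any(failed))
    message("logistic_assoc_additive: dropped ", sum(failed),
            " variant(s) (non-converged, separated or degenerate)")
  v <- table$variants[!failed, , drop = FALSE]
  out <- data.frame(
    chrom = v$chrom, bp = v$bp, snp_id = v$snp_id, a1 = v$alt,
    odds_ratio = or[!failed],
    p_value = pmin(1, pmax(pv[!failed], .Machine$double.xmin)),
    stringsAsFactors = FALSE
  )
  out$neg_log_p <- -log10(out$p_value)
  out <- sort_by_locus(out)
  rownames(out) <- NULL
  attr(out, "n_failed") <- sum(failed)
  out
}
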