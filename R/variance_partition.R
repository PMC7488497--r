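#' Residualize expression on one ancestry representation
#'
#' OLS of the expression vector on an intercept plus the supplied ancestry
#' covariates (five genotype PCs for global ancestry; AFR and ASN allele
#' counts at the gene's TSS for local ancestry); returns the residual.
#' Constant covariate columns are dropped; remaining collinearity is an
#' error.
#'
#' @param y Expression vector.
#' @param covariates Numeric matrix of ancestry covariates (samples x m).
#' @return Residual vector.
#' @export
residualize <- function(y, covariates) {
  dc <- drop_constant_cols(covariates)
  X <- cbind(`(Intercept)` = 1, dc$x)
  if (length(y) <= ncol(X) + 1L)
    stop("too few samples (", length(y), ") for ", ncol(X) - 1L,
         " covariates", call. = FALSE)
  fit <- ols_stats(y, X)
  if (fit$rank < ncol(X)) {
    aliased <- colnames(X)[is.na(fit$coef)]
    stop("rank-deficient covariates after dropping constants: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  fit$residuals
}

#' Variance in a residual explained by the other ancestry representation
#'
#' Coefficient of determination from OLS of the residual on an intercept plus
#' the other representation's covariates. If every covariate column is
#' constant the explained variance is 0.
#'
#' @param residual Residual vector from [residualize()].
#' @param other_covariates Numeric matrix of the other representation's
#'   covariates.
#' @return R-squared in \[0, 1\].
#' @export
variance_explained <- function(residual, other_covariates) {
  dc <- drop_constant_cols(other_covariates)
  if (ncol(dc$x) == 0L) return(0)
  X <- cbind(`(Intercept)` = 1, dc$x)
  if (length(residual) <= ncol(X) + 1L)
    stop("too few samples for the requested covariates", call. = FALSE)
  fit <- ols_stats(residual, X)
  if (fit$rank < ncol(X)) {
    aliased <- colnames(X)[is.na(fit$coef)]
    stop("rank-deficient covariates after dropping constants: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  fit$r_squared
}

#' Two-step variance partition of expression between local and global ancestry
#'
#' For every gene, runs both directions of the two-step regression: variance
#' in expression residualized on global ancestry (five genotype PCs) that is
#' explained by local ancestry at the TSS (AFR and ASN allele counts), and
#' vice versa. Samples with unknown local ancestry at a gene's TSS are
#' dropped for that gene (both directions, so the per-gene comparison stays
#' paired). The two per-gene R-squared distributions are compared with a
#' paired two-sided t test, and the fraction of genes where local ancestry
#' explains at least `tail_r2` of the residual variance is reported.
#'
#' @param expression Genes x samples matrix.
#' @param la_tss List of genes x samples count matrices (`afr`, `asn`, `unk`)
#'   as from [la_counts()] evaluated at the gene TSSs.
#' @param gpcs Samples x components matrix of genotype PC scores (first five
#'   are used).
#' @param tissue Tissue label carried into the records.
#' @param tail_r2 Tail threshold on the LA-after-GA R-squared; default 0.07.
#' @return List: `records` (gene_id, tissue, direction, r_squared,
#'   n_samples), `t_test` (paired htest, GA-after-LA minus LA-after-GA),
#'   `frac_la_tail`.
#' @export
run_variance_partition <- function(expression, la_tss, gpcs,
                                   tissue = "tissue1", tail_r2 = 0.07) {
  genes <- rownames(expression)
  if (is.null(genes) || nrow(expression) == 0L)
    stop("no genes in the expression matrix", call. = FALSE)
  samples <- colnames(expression)
  gpcs <- gpcs[samples, seq_len(min(5L, ncol(gpcs))), drop = FALSE]
  recs <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    ok <- la_tss$unk[g, samples] == 0L
    y <- expression[g, samples][ok]
    la <- cbind(AFR = la_tss$afr[g, samples][ok],
                ASN = la_tss$asn[g, samples][ok])
    ga <- gpcs[ok, , drop = FALSE]
    r2_la_after_ga <- variance_explained(residualize(y, ga), la)
    r2_ga_after_la <- variance_explained(residualize(y, la), ga)
    recs[[gi]] <- data.frame(
      gene_id = g, tissue = tissue,
      direction = c("LA_after_GA", "GA_after_LA"),
      r_squared = c(r2_la_after_ga, r2_ga_after_la),
      n_samples = sum(ok), stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  la_r2 <- records$r_squared[records$direction == "LA_after_GA"]
  ga_r2 <- records$r_squared[records$direction == "GA_after_LA"]
  tt <- stats::t.test(ga_r2, la_r2, paired = TRUE)
  list(records = records, t_test = tt,
       frac_la_tail = mean(la_r2 >= tail_r2))
}
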