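# Independent oracles kept deliberately naive: normal equations for OLS,
# explicit configuration enumeration for the colocalization posteriors.

ols_oracle <- function(y, X) {
  xtx <- crossprod(X)
  beta <- solve(xtx, crossprod(X, y))
  resid <- drop(y - X %*% beta)
  df <- length(y) - ncol(X)
  sigma2 <- sum(resid^2) / df
  tss <- sum((y - mean(y))^2)
  list(coef = drop(beta), se = sqrt(diag(solve(xtx)) * sigma2), df = df,
       residuals = resid, r_squared = 1 - sum(resid^2) / tss)
}

# Posterior of the five sharing hypotheses by brute-force enumeration over
# every single-variant and variant-pair causal configuration.
coloc_enum_oracle <- function(gwas, eqtl, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  bf1 <- exp(wakefield_labf(gwas))
  bf2 <- exp(wakefield_labf(eqtl))
  k <- length(bf1)
  w <- c(H0 = 1, H1 = sum(p1 * bf1), H2 = sum(p2 * bf2), H3 = 0,
         H4 = sum(p12 * bf1 * bf2))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j) w["H3"] <- w["H3"] + p1 * p2 * bf1[i] * bf2[j]
    }
  }
  unname(w / sum(w))
}

# Random summary-statistics table shaped like one side of a locus.
random_sumstats <- function(k, n = 500, z = NULL) {
  se <- stats::runif(k, 0.05, 0.2)
  if (is.null(z)) z <- stats::rnorm(k)
  data.frame(variant_id = sprintf("v%02d", seq_len(k)), beta = z * se,
             se = se, z = z, pvalue = 2 * stats::pnorm(-abs(z)), n = n,
             case_fraction = NA_real_, trait_type = "quant",
             stringsAsFactors = FALSE)
}

# Small shared cohort for tests that only need plausibly structured data.
tiny_cohort <- function(seed = 42, ...) {
  simulate_cohort(sim_config(n_individuals = 40L, n_chromosomes = 2L,
                             n_variants_per_chrom = 150L,
                             chrom_length_bp = 2e7, chrom_length_morgans = 0.2,
                             n_genes = 12L, seed = seed, ...))
}

# Tract table helper for hand-built cases.
tract_row <- function(sample_id, hap, chrom, start, end, ancestry) {
  data.frame(sample_id = sample_id, haplotype_index = hap, chrom = chrom,
             start = start, end = end, ancestry = ancestry,
             stringsAsFactors = FALSE)
}
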