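#' Simulation configuration for a synthetic admixed cohort
#'
#' Bundles every tunable of the synthetic-cohort generator: cohort and genome
#' dimensions, the Balding-Nichols differentiation of the three ancestral
#' populations, the Dirichlet prior on per-individual global-ancestry
#' proportions, the recombination clock, and the expression / GWAS
#' architectures layered on top of the genotypes.
#'
#' The defaults describe the study conditions the package's analyses assume: a
#' cohort of 117 admixed individuals drawn from three ancestral populations
#' (EUR, AFR, ASN) differentiated at F_ST = 0.15 each, Dirichlet(3, 2, 1)
#' admixture proportions, 8 generations since admixture, and a linear genetic
#' map of 1 Morgan per 100 Mb.
#'
#' @param n_individuals Number of diploid individuals in the cohort.
#' @param n_chromosomes Number of (autosomal) chromosomes to simulate.
#' @param chrom_length_bp Physical length of each chromosome, in bp.
#' @param chrom_length_morgans Genetic length of each chromosome, in Morgans.
#' @param n_variants_per_chrom Number of biallelic variants per chromosome.
#' @param populations Ordered ancestral population labels; fixed at
#'   `c("EUR", "AFR", "ASN")`.
#' @param fst_per_population Balding-Nichols differentiation parameter F for
#'   each population, each in (0, 1).
#' @param dirichlet_alpha Positive Dirichlet concentration per population for
#'   the global-ancestry proportions.
#' @param generations_since_admixture Generations g since the admixture event;
#'   tract breakpoints arrive as a Poisson process with rate g per Morgan.
#' @param n_genes Number of genes with simulated expression.
#' @param n_tissues Number of independent expression draws ("tissues") sharing
#'   one set of genotypes.
#' @param eqtl_fraction Fraction of genes given a true cis-eQTL effect.
#' @param effect_size_sd SD of the causal effect beta (expression SD units per
#'   alternate allele).
#' @param ancestry_expression_effect_sd SD of the per-gene effects of the AFR
#'   and ASN local-ancestry allele counts at the TSS on expression.
#' @param noise_sd SD of the residual expression noise.
#' @param gwas_n Sample size of the independently simulated GWAS cohort.
#' @param gwas_shared_fraction Fraction of eGene-linked GWAS traits whose
#'   causal variant is the eQTL causal variant (the rest use a distinct
#'   variant in the same cis window).
#' @param seed Integer seed; identical configurations produce byte-identical
#'   cohorts.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 117L,
                       n_chromosomes = 2L,
                       chrom_length_bp = 5e7,
                       chrom_length_morgans = 0.5,
                       n_variants_per_chrom = 1000L,
                       populations = c("EUR", "AFR", "ASN"),
                       fst_per_population = c(EUR = 0.15, AFR = 0.15, ASN = 0.15),
                       dirichlet_alpha = c(EUR = 3, AFR = 2, ASN = 1),
                       generations_since_admixture = 8,
                       n_genes = 50L,
                       n_tissues = 1L,
                       eqtl_fraction = 0.3,
                       effect_size_sd = 0.8,
                       ancestry_expression_effect_sd = 0.5,
                       noise_sd = 1,
                       gwas_n = 1000L,
                       gwas_shared_fraction = 0.5,
                       seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.numeric(chrom_length_bp),
    chrom_length_morgans = as.numeric(chrom_length_morgans),
    n_variants_per_chrom = as.integer(n_variants_per_chrom),
    populations = as.character(populations),
    fst_per_population = unname(fst_per_population),
    dirichlet_alpha = unname(dirichlet_alpha),
    generations_since_admixture = as.numeric(generations_since_admixture),
    n_genes = as.integer(n_genes),
    n_tissues = as.integer(n_tissues),
    eqtl_fraction = as.numeric(eqtl_fraction),
    effect_size_sd = as.numeric(effect_size_sd),
    ancestry_expression_effect_sd = as.numeric(ancestry_expression_effect_sd),
    noise_sd = as.numeric(noise_sd),
    gwas_n = as.integer(gwas_n),
    gwas_shared_fraction = as.numeric(gwas_shared_fraction),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_individuals", "n_chromosomes", "n_variants_per_chrom",
              "n_genes", "n_tissues", "gwas_n")
  for (nm in counts) {
    if (length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]) || cfg[[nm]] < 1L)
      stop("configuration error: `", nm, "` must be a positive count",
           call. = FALSE)
  }
  if (length(cfg$populations) != 3L)
    stop("configuration error: exactly three ancestral populations required",
         call. = FALSE)
  if (length(cfg$fst_per_population) != 3L ||
      any(cfg$fst_per_population <= 0) || any(cfg$fst_per_population >= 1))
    stop("configuration error: fst_per_population must be three values in (0, 1)",
         call. = FALSE)
  if (length(cfg$dirichlet_alpha) != 3L || any(cfg$dirichlet_alpha <= 0))
    stop("configuration error: dirichlet_alpha must be three positive values",
         call. = FALSE)
  if (cfg$generations_since_admixture <= 0)
    stop("configuration error: generations_since_admixture must be positive",
         call. = FALSE)
  if (cfg$chrom_length_bp <= 0 || cfg$chrom_length_morgans <= 0)
    stop("configuration error: chromosome lengths must be positive",
         call. = FALSE)
  sds <- c("effect_size_sd", "ancestry_expression_effect_sd", "noise_sd")
  for (nm in sds) {
    if (cfg[[nm]] < 0)
      stop("configuration error: `", nm, "` must be nonnegative", call. = FALSE)
  }
  fracs <- c("eqtl_fraction", "gwas_shared_fraction")
  for (nm in fracs) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop("configuration error: `", nm, "` must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$gwas_n < 30L)
    stop("configuration error: gwas_n must be at least 30 ",
         "(marginal summary statistics are unstable below that)", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic admixed-cohort configuration\n")
  cat(sprintf("  individuals: %d   chromosomes: %d x %.3g Mb (%.3g M)\n",
              x$n_individuals, x$n_chromosomes, x$chrom_length_bp / 1e6,
              x$chrom_length_morgans))
  cat(sprintf("  variants/chrom: %d   genes: %d   tissues: %d\n",
              x$n_variants_per_chrom, x$n_genes, x$n_tissues))
  cat(sprintf("  populations: %s (F = %s)\n",
              paste(x$populations, collapse = "/"),
              paste(format(x$fst_per_population), collapse = "/")))
  cat(sprintf("  Dirichlet alpha: %s   g = %g generations\n",
              paste(format(x$dirichlet_alpha), collapse = "/"),
              x$generations_since_admixture))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Dirichlet draws via normalized gammas.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

sample_ids <- function(n) sprintf("S%04d", seq_len(n))
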