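test_that("Balding-Nichols panel has the right limits and moments", {
  set.seed(1)
  cfg_lo <- sim_config(n_variants_per_chrom = 1000L, n_chromosomes = 1L,
                       fst_per_population = rep(1e-4, 3L))
  panel <- draw_ancestral_panel(cfg_lo)
  # F -> 0: population frequencies collapse onto the ancestral frequency
  for (pop in c("EUR", "AFR", "ASN")) {
    expect_lt(mean(abs(panel$pop_freq[, pop] -
                         panel$variants$ancestral_freq)), 0.02)
  }
  # F = 0.5: Var(p_k | p) = p (1 - p) F, checked in a narrow ancestral bin
  set.seed(2)
  cfg_hi <- sim_config(n_variants_per_chrom = 10000L, n_chromosomes = 1L,
                       fst_per_population = rep(0.5, 3L))
  panel_hi <- draw_ancestral_panel(cfg_hi)
  bin <- abs(panel_hi$variants$ancestral_freq - 0.5) < 0.05
  expect_gt(sum(bin), 500)
  v_emp <- stats::var(panel_hi$pop_freq[bin, "AFR"])
  expect_lt(abs(v_emp - 0.125) / 0.125, 0.10)
  # positions strictly increasing per chromosome
  expect_true(!is.unsorted(panel$variants$pos, strictly = TRUE))
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_individuals = 20L, n_variants_per_chrom = 50L,
                    n_genes = 5L, seed = 99L)
  a <- suppressWarnings(simulate_cohort(cfg))
  b <- suppressWarnings(simulate_cohort(cfg))
  expect_identical(a$haplotypes, b$haplotypes)
  expect_identical(a$tracts, b$tracts)
  expect_identical(a$expression, b$expression)
  expect_identical(a$truth, b$truth)
})

test_that("tract simulation follows the Poisson recombination clock", {
  cfg <- sim_config(n_individuals = 1000L, n_chromosomes = 1L,
                    chrom_length_bp = 1e8, chrom_length_morgans = 1,
                    generations_since_admixture = 8)
  props <- matrix(1 / 3, nrow = 1000L, ncol = 3L)
  set.seed(3)
  tr <- simulate_tracts(cfg, props)
  # after merging, a raw Poisson(g * L) breakpoint survives only when the
  # flanking segments differ in ancestry: expected boundaries g*L*(1 - sum p^2)
  key <- paste(tr$sample_id, tr$haplotype_index)
  boundaries <- table(key) - 1L
  expected <- 8 * (1 - sum(rep(1 / 3, 3L)^2))
  expect_lt(abs(mean(boundaries) - expected) / expected, 0.05)
  # single-ancestry proportions give one merged tract per haplotype
  tr1 <- simulate_tracts(cfg, matrix(c(1, 0, 0), nrow = 1))
  expect_equal(nrow(tr1), 2L)
  expect_true(all(tr1$ancestry == "EUR"))
  expect_equal(tr1$start, c(0, 0))
  expect_equal(tr1$end, c(1e8, 1e8))
  # tiling: each haplotype's tracts partition [0, L)
  one <- tr[key == key[1L], ]
  one <- one[order(one$start), ]
  expect_equal(one$start[1L], 0)
  expect_equal(one$end[nrow(one)], 1e8)
  if (nrow(one) > 1L)
    expect_equal(one$start[-1L], one$end[-nrow(one)])
  expect_error(simulate_tracts(cfg, matrix(c(0.5, 0.2, 0.2), nrow = 1)),
               "sum to 1")
})

test_that("haplotype alleles follow the covering tract's population frequency", {
  set.seed(4)
  cfg <- sim_config(n_individuals = 500L, n_chromosomes = 1L,
                    n_variants_per_chrom = 300L, chrom_length_bp = 5e7,
                    chrom_length_morgans = 0.5, n_genes = 2L, seed = 5L)
  co <- simulate_cohort(cfg)
  expect_true(all(co$haplotypes %in% c(0L, 1L)))
  expect_true(all(co$dosages %in% 0:2))
  # conditional frequency recovery on AFR-labeled haplotype-sites
  afr_mask <- co$hap_ancestry == "AFR"
  n_afr <- rowSums(afr_mask)
  emp <- rowSums(co$haplotypes * afr_mask) / n_afr
  use <- n_afr >= 100
  expect_gt(sum(use), 100)
  expect_lt(mean(abs(emp[use] - co$panel$pop_freq[use, "AFR"])), 0.03)
  # conservation: every variant carries exactly 2n ancestry-labeled alleles
  expect_true(all(rowSums(!is.na(co$hap_ancestry)) ==
                    2L * cfg$n_individuals))
})

test_that("zero population frequency yields monomorphic reference haplotypes", {
  variants <- data.frame(chrom = "chr1", pos = c(100L, 200L), ref = "A",
                         alt = "G", stringsAsFactors = FALSE)
  variants$variant_id <- paste("chr1", variants$pos, "A", "G", sep = "_")
  variants$ancestral_freq <- 0.5
  panel <- structure(list(variants = variants,
                          pop_freq = matrix(0, 2, 3,
                                            dimnames = list(variants$variant_id,
                                                            c("EUR", "AFR", "ASN"))),
                          populations = c("EUR", "AFR", "ASN")),
                     class = "ancestral_panel")
  tr <- rbind(tract_row("S1", 0L, "chr1", 0, 1000, "EUR"),
              tract_row("S1", 1L, "chr1", 0, 1000, "AFR"))
  geno <- simulate_genotypes(panel, tr)
  expect_true(all(geno$haplotypes == 0L))
})

test_that("expression follows the additive model exactly when noiseless", {
  cfg <- tiny_cohort(seed = 6)$config
  cfg$noise_sd <- 0
  cfg$ancestry_expression_effect_sd <- 0
  cfg$eqtl_fraction <- 1
  co <- simulate_cohort(cfg)
  tr <- co$truth
  for (i in which(tr$is_egene)) {
    g <- tr$gene_id[i]
    expect_equal(unname(co$expression[[1L]][g, ]),
                 unname(tr$beta[i] * co$dosages[tr$causal_variant[i], ]),
                 tolerance = 1e-12)
  }
  # global-null construction: no eGenes, pure noise
  cfg$eqtl_fraction <- 0
  cfg$noise_sd <- 1
  co0 <- simulate_cohort(cfg)
  expect_false(any(co0$truth$is_egene))
  expect_lt(abs(stats::sd(co0$expression[[1L]]) - 1), 0.1)
})

test_that("regression on dosage plus true ancestry counts recovers beta", {
  cfg <- sim_config(n_individuals = 200L, n_chromosomes = 2L,
                    n_variants_per_chrom = 400L, n_genes = 100L,
                    eqtl_fraction = 1, seed = 7L)
  co <- simulate_cohort(cfg)
  tr <- co$truth[co$truth$is_egene & !is.na(co$truth$causal_variant), ]
  sites <- co$panel$variants[
    co$panel$variants$variant_id %in% tr$causal_variant,
    c("chrom", "pos", "variant_id")]
  la <- la_counts(co$tracts, sites, samples = co$sample_ids)
  # the expression model also carries ancestry terms at the TSS
  tss_sites <- data.frame(chrom = co$gene_annot$chrom, pos = co$gene_annot$tss,
                          variant_id = co$gene_annot$gene_id)
  la_tss <- la_counts(co$tracts, tss_sites, samples = co$sample_ids)
  hit <- logical(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    g <- tr$gene_id[i]
    X <- cbind(1, v = co$dosages[tr$causal_variant[i], ],
               la_tss$afr[g, ], la_tss$asn[g, ])
    fit <- admixqtl:::ols_stats(co$expression[[1L]][g, ], X)
    hit[i] <- abs(fit$coef[2L] - tr$beta[i]) <= 2 * fit$se[2L]
  }
  expect_gt(mean(hit), 0.88)
})

test_that("GWAS marginal statistics are definitionally consistent and calibrated", {
  co <- tiny_cohort(seed = 8, eqtl_fraction = 1, gwas_n = 200)
  gw <- simulate_gwas(co, co$config)
  st <- do.call(rbind, gw$stats)
  ok <- !is.na(st$beta)
  expect_equal(st$z[ok], st$beta[ok] / st$se[ok])
  expect_true(all(st$n == 200L))
  # null calibration: a trait with no causal variant has uniform p-values
  set.seed(9)
  cfg <- sim_config(n_individuals = 300L, n_chromosomes = 1L,
                    n_variants_per_chrom = 2000L, n_genes = 2L, seed = 10L)
  co2 <- simulate_cohort(cfg)
  hits5 <- 0L
  hits05 <- 0L
  n_tests <- 0L
  for (r in seq_len(500L)) {
    y <- stats::rnorm(300L)
    p <- marginal_stats(co2$dosages, y)$pvalue
    p <- p[!is.na(p)]
    hits5 <- hits5 + sum(p < 1e-5)
    hits05 <- hits05 + sum(p < 0.05)
    n_tests <- n_tests + length(p)
  }
  expect_gte(n_tests, 9e5)   # monomorphic variants drop a handful of tests
  expect_lt(hits5 / n_tests, 5e-5)          # ~1e-5 expected
  expect_lt(abs(hits05 / n_tests - 0.05), 0.01)
})

test_that("realized global ancestry tracks the Dirichlet prior", {
  cfg <- sim_config(n_individuals = 400L, n_chromosomes = 2L,
                    n_variants_per_chrom = 50L, n_genes = 2L, seed = 12L)
  co <- suppressWarnings(simulate_cohort(cfg))
  expect_equal(unname(rowSums(co$true_global_ancestry)),
               rep(1, 400L), tolerance = 1e-9)
  target <- cfg$dirichlet_alpha / sum(cfg$dirichlet_alpha)
  expect_lt(max(abs(colMeans(co$true_global_ancestry) - target)), 0.04)
})
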