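#' Type-I error calibration of the three adjustment models
#'
#' Two simulated arms, no true eQTL effects in either. Null arm: expression
#' is pure noise; the fraction of cis association tests with p < 0.05 is
#' recorded for LocalAA and GlobalAA. Stratified arm: expression carries
#' ancestry-stratified components (effects of the AFR/ASN allele counts at
#' the TSS, sd `strat_sd`) but still no genetic effect; rates are recorded
#' for an unadjusted model (no covariates) and for both adjustments. Local
#' ancestry is taken from simulator truth; genotype PCs are computed from
#' the MAC-filtered dosages. No technical covariates or hidden-confounder
#' PCs are included, so the comparison isolates the ancestry adjustments.
#'
#' @param n_genes,n_individuals Arm dimensions; defaults 200 x 200.
#' @param fst Balding-Nichols differentiation; default 0.15.
#' @param strat_sd SD of the stratified-arm ancestry effects; default 1.
#' @param seed Seed for both arms.
#' @return List of p < 0.05 rates (`null_local`, `null_global`,
#'   `strat_unadjusted`, `strat_local`, `strat_global`) plus `n_tests`.
#' @export
experiment_type1 <- function(n_genes = 200L, n_individuals = 200L,
                             fst = 0.15, strat_sd = 1, seed = 1L) {
  rate <- function(recs) {
    ok <- !recs$skipped
    mean(recs$p_value[ok] < 0.05)
  }
  arm <- function(strat, seed) {
    cfg <- sim_config(n_individuals = n_individuals, n_genes = n_genes,
                      n_chromosomes = 2L, n_variants_per_chrom = 600L,
                      fst_per_population = rep(fst, 3L),
                      eqtl_fraction = 0, effect_size_sd = 0,
                      ancestry_expression_effect_sd = if (strat) strat_sd else 0,
                      seed = seed)
    co <- simulate_cohort(cfg)
    kept <- mac_filter(co$dosages)
    sites <- co$panel$variants[co$panel$variants$variant_id %in% kept,
                               c("chrom", "pos", "variant_id")]
    la <- la_counts(co$tracts, sites, samples = co$sample_ids)
    pcs <- genotype_pca(co$dosages[kept, , drop = FALSE])
    cis <- cis_pairs(co$gene_annot, sites)
    expr <- co$expression[[1L]]
    out <- list(
      local = rate(map_eqtls(expr, co$dosages, cis, la = la,
                             method = "local")),
      global = rate(map_eqtls(expr, co$dosages, cis, gpcs = pcs$scores,
                              method = "global")),
      n_tests = sum(lengths(cis)))
    if (strat)
      out$unadjusted <- rate(map_eqtls(expr, co$dosages, cis,
                                       method = "unadjusted"))
    out
  }
  null_arm <- arm(FALSE, seed)
  strat_arm <- arm(TRUE, seed + 1L)
  list(null_local = null_arm$local, null_global = null_arm$global,
       strat_unadjusted = strat_arm$unadjusted,
       strat_local = strat_arm$local, strat_global = strat_arm$global,
       n_tests = null_arm$n_tests + strat_arm$n_tests)
}

#' Effect-size recovery at the causal variant
#'
#' Simulates eGenes under a purely additive architecture (every gene an
#' eGene, no ancestry-stratified component) and fits both adjustments at the
#' true causal variant; reports the fraction of genes whose true beta lies
#' within the estimate +/- 1.96 standard errors.
#'
#' @param n_egenes,n_individuals Dimensions; defaults 500 x 200.
#' @param seed Seed.
#' @return List: `coverage_local`, `coverage_global`, `n_egenes`.
#' @export
experiment_recovery <- function(n_egenes = 500L, n_individuals = 200L,
                                seed = 1L) {
  cfg <- sim_config(n_individuals = n_individuals, n_genes = n_egenes,
                    n_chromosomes = 2L, n_variants_per_chrom = 600L,
                    eqtl_fraction = 1, ancestry_expression_effect_sd = 0,
                    seed = seed)
  co <- simulate_cohort(cfg)
  truth <- co$truth[co$truth$is_egene & !is.na(co$truth$causal_variant), ]
  sites <- co$panel$variants[
    co$panel$variants$variant_id %in% truth$causal_variant,
    c("chrom", "pos", "variant_id")]
  la <- la_counts(co$tracts, sites, samples = co$sample_ids)
  kept <- mac_filter(co$dosages)
  pcs <- genotype_pca(co$dosages[kept, , drop = FALSE])
  expr <- co$expression[[1L]]
  covers <- function(rec, b) !rec$skipped &&
    abs(rec$beta - b) <= 1.96 * rec$se
  cov_l <- cov_g <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    g <- truth$gene_id[i]
    vid <- truth$causal_variant[i]
    y <- expr[g, ]
    v <- co$dosages[vid, ]
    none <- matrix(numeric(0), nrow = length(y), ncol = 0L)
    cov_l[i] <- covers(fit_local(y, v, none, la$afr[vid, ], la$asn[vid, ],
                                 la$unk[vid, ]), truth$beta[i])
    cov_g[i] <- covers(fit_global(y, v, none, pcs$scores), truth$beta[i])
  }
  list(coverage_local = mean(cov_l), coverage_global = mean(cov_g),
       n_egenes = nrow(truth))
}

#' Colocalization discrimination between shared and distinct causal variants
#'
#' Simulates an eQTL cohort in which every gene is an eGene and a GWAS
#' cohort in which half the traits share the eQTL causal variant; scores
#' every seedable locus with COLOC and the single-causal CLPP, and reports
#' median PP4 and CLPP by sharing status.
#'
#' @param n_genes Number of eGene-linked traits to attempt; default 130
#'   (roughly half the traits produce a genome-wide seed, so this yields
#'   >= 50 seedable loci).
#' @param n_individuals eQTL cohort size; default 200.
#' @param gwas_n GWAS cohort size; default 1000.
#' @param seed Seed.
#' @return List: `median_pp4_shared`, `median_pp4_distinct`,
#'   `median_clpp_shared`, `median_clpp_distinct`, `n_loci`, `per_locus`.
#' @export
experiment_discrimination <- function(n_genes = 130L, n_individuals = 200L,
                                      gwas_n = 1000L, seed = 1L) {
  cfg <- sim_config(n_individuals = n_individuals, n_genes = n_genes,
                    n_chromosomes = 2L, n_variants_per_chrom = 600L,
                    eqtl_fraction = 1, effect_size_sd = 1,
                    ancestry_expression_effect_sd = 0,
                    gwas_n = gwas_n, gwas_shared_fraction = 0.5, seed = seed)
  co <- simulate_cohort(cfg)
  gwas <- simulate_gwas(co, cfg)
  v <- co$panel$variants
  expr <- co$expression[[1L]]
  rows <- list()
  for (j in seq_len(nrow(gwas$traits))) {
    tid <- gwas$traits$trait_id[j]
    g <- gwas$traits$gene_id[j]
    gstats <- gwas$stats[[tid]]
    seeds <- scan_seeds(gstats)
    if (nrow(seeds) == 0L) next
    gi <- match(g, co$gene_annot$gene_id)
    win <- v$chrom == co$gene_annot$chrom[gi] &
      abs(v$pos - co$gene_annot$tss[gi]) <= 1e6
    estats <- marginal_stats(co$dosages[win, , drop = FALSE], expr[g, ])
    estats <- cbind(estats, v[win, c("chrom", "pos", "ref", "alt")])
    estats$case_fraction <- NA_real_
    estats$trait_type <- "quant"
    locus <- build_locus(seeds[1L, ], gstats, estats)
    if (is.null(locus)) next
    sc <- score_locus(locus)
    rows[[tid]] <- data.frame(trait_id = tid, gene_id = g,
                              shared = gwas$traits$shared[j],
                              pp4 = unname(sc$pp["PP4"]), clpp = sc$clpp,
                              n_variants = length(locus$variants),
                              stringsAsFactors = FALSE)
  }
  per_locus <- do.call(rbind, rows)
  rownames(per_locus) <- NULL
  med <- function(x) if (length(x) == 0L) NA_real_ else stats::median(x)
  list(median_pp4_shared = med(per_locus$pp4[per_locus$shared]),
       median_pp4_distinct = med(per_locus$pp4[!per_locus$shared]),
       median_clpp_shared = med(per_locus$clpp[per_locus$shared]),
       median_clpp_distinct = med(per_locus$clpp[!per_locus$shared]),
       n_loci = nrow(per_locus), per_locus = per_locus)
}
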