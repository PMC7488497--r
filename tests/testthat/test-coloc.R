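gwas_table <- function(pos, pvalue, chrom = "chr1") {
  data.frame(variant_id = sprintf("%s_%d_A_G", chrom, pos), chrom = chrom,
             pos = pos, pvalue = pvalue, stringsAsFactors = FALSE)
}

test_that("seed scanning is greedy by p with a 1 Mb exclusion window", {
  expect_equal(nrow(scan_seeds(gwas_table(100L, 1e-6))), 1L)
  g2 <- gwas_table(c(1e6, 1.5e6), c(1e-6, 1e-8))
  s2 <- scan_seeds(g2)
  expect_equal(nrow(s2), 1L)
  expect_equal(s2$pos, 1.5e6)
  expect_equal(nrow(scan_seeds(gwas_table(100L, 1e-4))), 0L)
  # beyond the window, both seed
  g3 <- gwas_table(c(1e6, 3.5e6), c(1e-8, 1e-6))
  expect_equal(nrow(scan_seeds(g3)), 2L)
})

test_that("locus construction gates on the eQTL p-value and harmonizes alleles", {
  full <- function(pos, p, ref = "A", alt = "G", beta = 0.1, chrom = "chr1") {
    data.frame(variant_id = sprintf("%s_%d_%s_%s", chrom, pos, ref, alt),
               chrom = chrom, pos = pos, ref = ref, alt = alt, beta = beta,
               se = 0.05, z = beta / 0.05, pvalue = p, n = 500L,
               case_fraction = NA_real_, trait_type = "quant",
               stringsAsFactors = FALSE)
  }
  seed <- data.frame(variant_id = "chr1_500000_A_G", chrom = "chr1",
                     pos = 5e5, pvalue = 1e-8, stringsAsFactors = FALSE)
  gw <- full(c(4e5, 5e5, 6e5, 7e5), c(1e-3, 1e-8, 0.5, 0.2))
  eq <- full(c(4e5, 5e5, 6e5), c(1e-3, 5e-4, 0.9))
  expect_null(build_locus(seed, gw, eq))       # best eQTL p 5e-4 >= 1e-4
  eq$pvalue[2L] <- 1e-5
  loc <- build_locus(seed, gw, eq)
  expect_s3_class(loc, "coloc_locus")
  expect_equal(length(loc$variants), 3L)       # intersection drops pos 7e5
  # swapped ref/alt flips the GWAS effect
  gw_fl <- gw
  gw_fl$ref[1L] <- "G"
  gw_fl$alt[1L] <- "A"
  loc_fl <- build_locus(seed, gw_fl, eq)
  expect_equal(loc_fl$gwas$beta[1L], -gw$beta[1L])
  expect_equal(loc_fl$gwas$z[1L], -gw$z[1L])
  # irreconcilable alleles are dropped
  gw_bad <- gw
  gw_bad$ref[1L] <- "T"
  expect_message(loc_bad <- build_locus(seed, gw_bad, eq), "unresolvable")
  expect_equal(length(loc_bad$variants), 2L)
})

test_that("COLOC posteriors match brute-force configuration enumeration", {
  set.seed(71)
  for (rep in 1:15) {
    k <- sample(2:10, 1L)
    gw <- random_sumstats(k, z = rnorm(k, sd = 3))
    eq <- random_sumstats(k, z = rnorm(k, sd = 3))
    locus <- structure(list(variants = gw$variant_id, gwas = gw, eqtl = eq),
                       class = "coloc_locus")
    pp <- coloc_pp(locus)
    expect_equal(sum(pp), 1, tolerance = 1e-12)
    expect_equal(unname(pp), coloc_enum_oracle(gw, eq), tolerance = 1e-9)
  }
})

test_that("COLOC calls the expected hypothesis in stylized loci", {
  null_stats <- random_sumstats(100L, z = rep(0, 100L))
  locus0 <- structure(list(variants = null_stats$variant_id,
                           gwas = null_stats, eqtl = null_stats),
                      class = "coloc_locus")
  pp0 <- coloc_pp(locus0)
  expect_equal(names(which.max(pp0)), "PP0")
  set.seed(72)
  z <- rnorm(50L, sd = 0.5)
  z[25L] <- 10
  shared_g <- random_sumstats(50L, z = z)
  shared_e <- random_sumstats(50L, z = z + rnorm(50L, sd = 0.2))
  locus4 <- structure(list(variants = shared_g$variant_id,
                           gwas = shared_g, eqtl = shared_e),
                      class = "coloc_locus")
  expect_gt(coloc_pp(locus4)["PP4"], 0.9)
})

test_that("single-causal PIPs normalize and respect symmetry", {
  one <- random_sumstats(1L, z = 3)
  expect_equal(single_causal_pips(one), 1)
  two <- random_sumstats(2L, z = c(4, -4))
  two$se <- c(0.1, 0.1)
  two$beta <- two$z * two$se
  expect_equal(single_causal_pips(two), c(0.5, 0.5))
  set.seed(73)
  many <- random_sumstats(20L)
  expect_equal(sum(single_causal_pips(many)), 1, tolerance = 1e-12)
})

test_that("CLPP reproduces its closed forms and monotone bounds", {
  expect_equal(clpp(1, 1), 1)
  expect_equal(clpp(c(0.5, 0.5), c(0.5, 0.5)), 0.4375)
  expect_equal(clpp(c(1, 0), c(0, 1)), 0)
  expect_error(clpp(c(0.5, 0.5), 1), "length")
  expect_error(clpp(c(0.9, 0.9), c(0.5, 0.5)), "at most 1")
  set.seed(74)
  for (rep in 1:20) {
    k <- sample(1:8, 1L)
    pg <- prop.table(runif(k))
    pe <- prop.table(runif(k))
    expect_lte(clpp(pg, pe), sum(pg * pe) + 1e-12)   # union bound
    # raising one PIP product never decreases CLPP (sub-normalized PIPs)
    pg_sub <- pg / 2
    v <- clpp(pg_sub, pe)
    pg_up <- pg_sub
    pg_up[1L] <- pg_up[1L] + 0.1
    expect_gte(clpp(pg_up, pe), v - 1e-12)
  }
})

test_that("concordance classification follows the strict threshold calls", {
  sc <- data.frame(
    locus_id = rep(c("L1", "L2", "L3"), each = 2L),
    adjustment = rep(c("LocalAA", "GlobalAA"), 3L),
    pp4 = c(0.9, 0.2, 0.6, 0.6, 0.9, 0.9),
    clpp = c(0.5, NA, 0.01, 0.01, 0.5, 0.5),
    stringsAsFactors = FALSE)
  out <- classify_concordance(sc)
  l1 <- out[out$locus_id == "L1", ]
  expect_true(l1$flagged)
  expect_equal(l1$direction, "LocalAA")
  # CLPP exactly 0.01 is not a call (strict >), so L2 passes nothing
  l2 <- out[out$locus_id == "L2", ]
  expect_false(l2$local_finemap)
  expect_false(l2$flagged)
  # both adjustments pass both methods: concordant, not flagged
  expect_false(out$flagged[out$locus_id == "L3"])
})
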