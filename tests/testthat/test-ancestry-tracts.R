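site_df <- function(pos, p_eur, p_afr, p_asn, sample_id = "S1", hap = 0L,
                    chrom = "chr1") {
  data.frame(sample_id = sample_id, haplotype_index = hap, chrom = chrom,
             pos = pos, p_EUR = p_eur, p_AFR = p_afr, p_ASN = p_asn,
             stringsAsFactors = FALSE)
}

test_that("posterior thresholding assigns at >= 0.9 and is inclusive", {
  d <- site_df(c(100L, 200L, 300L),
               p_eur = c(0.95, 0.50, 0.90),
               p_afr = c(0.03, 0.30, 0.05),
               p_asn = c(0.02, 0.20, 0.05))
  out <- assign_sites(d)
  expect_equal(out$ancestry, c("EUR", "UNK", "EUR"))
  bad <- site_df(100L, 0.5, 0.2, 0.2)
  expect_error(assign_sites(bad), "chr1:100")
})

test_that("run-length collapse uses BED half-open coordinates", {
  d <- site_df(c(100L, 200L, 300L), 1, 0, 0)
  d$ancestry <- "EUR"
  tr <- collapse_tracts(d)
  expect_equal(nrow(tr), 1L)
  expect_equal(c(tr$start, tr$end), c(99, 300))

  d2 <- site_df(c(10L, 20L, 30L, 40L), 1, 0, 0)
  d2$ancestry <- c("EUR", "EUR", "AFR", "AFR")
  tr2 <- collapse_tracts(d2)
  expect_equal(tr2$start, c(9, 29))
  expect_equal(tr2$end, c(20, 40))
  expect_equal(tr2$ancestry, c("EUR", "AFR"))

  expect_equal(nrow(collapse_tracts(d[0, ])), 0L)
  d3 <- d
  d3$pos <- c(100L, 100L, 300L)
  d3$ancestry <- "EUR"
  expect_error(collapse_tracts(d3), "strictly increasing")
})

test_that("collapse and expansion are mutually inverse at assayed sites", {
  set.seed(21)
  for (rep in 1:5) {
    pos <- sort(sample.int(1e6, 60L))
    labs <- sample(c("EUR", "AFR", "ASN", "UNK"), 60L, replace = TRUE)
    d <- site_df(pos, 1, 0, 0)
    d$ancestry <- labs
    tr <- collapse_tracts(d)
    back <- expand_tracts(tr, d[, c("sample_id", "haplotype_index", "chrom",
                                    "pos")])
    expect_identical(back$ancestry, labs)
    # adjacent tracts always differ in ancestry
    expect_true(all(tr$ancestry[-1L] != tr$ancestry[-nrow(tr)]))
  }
})

test_that("global fractions use assigned length with UNK reported separately", {
  tr <- tract_row("S1", 0L, "chr1", 0, 100, "EUR")
  ga <- global_fractions(tr)
  expect_equal(ga$EUR, 1)
  expect_equal(ga$unknown_fraction, 0)

  tr2 <- rbind(tract_row("S1", 0L, "chr1", 0, 50, "EUR"),
               tract_row("S1", 0L, "chr1", 50, 100, "AFR"))
  ga2 <- global_fractions(tr2)
  expect_equal(c(ga2$EUR, ga2$AFR), c(0.5, 0.5))

  tr3 <- rbind(tract_row("S1", 0L, "chr1", 0, 90e6, "EUR"),
               tract_row("S1", 0L, "chr1", 90e6, 100e6, "UNK"))
  ga3 <- global_fractions(tr3)
  expect_equal(ga3$EUR, 1)
  expect_equal(ga3$unknown_fraction, 0.1)

  expect_error(global_fractions(tract_row("S1", 0L, "chr1", 0, 10, "UNK")),
               "S1")
  # invariance to tract ordering
  shuffled <- tr2[c(2, 1), ]
  expect_equal(global_fractions(shuffled), ga2)
})

test_that("admixture selection is strict at the 90% cutoff", {
  ga <- data.frame(sample_id = c("a", "b", "c"),
                   EUR = c(0.85, 0.95, 0.90), AFR = c(0.15, 0.05, 0.10),
                   ASN = 0, unknown_fraction = 0, stringsAsFactors = FALSE)
  expect_equal(select_admixed(ga), "a")
})

test_that("MAC filter is inclusive at the threshold", {
  n <- 117L
  g <- rbind(five = c(rep(1L, 5L), rep(0L, n - 5L)),
             mono = rep(0L, n),
             ten = c(rep(1L, 10L), rep(0L, n - 10L)),
             common = c(rep(2L, 60L), rep(0L, n - 60L)))
  colnames(g) <- sprintf("S%03d", seq_len(n))
  kept <- mac_filter(g)
  expect_setequal(kept, c("ten", "common"))
  # "common" has 120 alt alleles of 234: minor is the reference allele
  expect_true("common" %in% kept)
})

test_that("local-ancestry allele counts sum to 2 and respect coverage", {
  tr <- rbind(tract_row("S1", 0L, "chr1", 0, 100, "EUR"),
              tract_row("S1", 1L, "chr1", 0, 100, "EUR"),
              tract_row("S2", 0L, "chr1", 0, 100, "EUR"),
              tract_row("S2", 1L, "chr1", 0, 50, "AFR"))
  sites <- data.frame(chrom = "chr1", pos = c(30L, 80L),
                      variant_id = c("v1", "v2"), stringsAsFactors = FALSE)
  cnt <- la_counts(tr, sites)
  expect_equal(unname(cnt$eur[, "S1"]), c(2L, 2L))
  expect_equal(unname(cnt$eur[, "S2"] + cnt$afr[, "S2"] + cnt$unk[, "S2"]),
               c(2L, 2L))
  # S2 hap1 covers only [0,50): v2 at pos 80 is unknown
  expect_equal(unname(cnt$unk[, "S2"]), c(0L, 1L))
  total <- cnt$eur + cnt$afr + cnt$asn + cnt$unk
  expect_true(all(total == 2L))
  # order invariance
  cnt2 <- la_counts(tr[sample.int(nrow(tr)), ], sites,
                    samples = c("S1", "S2"))
  expect_identical(cnt, cnt2)
  # overlap detection
  bad <- rbind(tract_row("S1", 0L, "chr1", 0, 60, "EUR"),
               tract_row("S1", 0L, "chr1", 40, 100, "AFR"))
  expect_error(la_counts(bad, sites), "overlapping")
})

test_that("the degenerate-posterior path reproduces simulator truth", {
  co <- tiny_cohort(seed = 31)
  post <- emit_site_posteriors(co)
  labels <- assign_sites(post)
  # truth at assayed sites
  key <- paste(labels$sample_id, labels$haplotype_index, sep = ".")
  truth_lab <- co$hap_ancestry[cbind(match(paste(labels$chrom, labels$pos),
                                           paste(co$panel$variants$chrom,
                                                 co$panel$variants$pos)),
                                     match(key, colnames(co$hap_ancestry)))]
  expect_identical(labels$ancestry, unname(truth_lab))
  # blurred posteriors produce UNK sites
  set.seed(32)
  post_b <- emit_site_posteriors(co, blur_rate = 0.2, blur_max = 0.85)
  lab_b <- assign_sites(post_b)
  expect_gt(mean(lab_b$ancestry == "UNK"), 0.1)
  expect_lt(mean(lab_b$ancestry == "UNK"), 0.3)
})
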