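test_that("covariate construction drops constants and yields orthogonal ePCs", {
  set.seed(61)
  n <- 30L
  expr <- matrix(rnorm(10L * n), nrow = 10L,
                 dimnames = list(sprintf("G%02d", 1:10), sprintf("S%02d", 1:n)))
  info <- data.frame(sex = rep("M", n), platform = rep(c("A", "B"), n / 2),
                     row.names = colnames(expr), stringsAsFactors = FALSE)
  expect_message(cv <- build_covariates(info, expr, n_hidden = 2L),
                 "constant covariate")
  expect_false(any(grepl("sex", colnames(cv))))
  expect_true(any(grepl("platform", colnames(cv))))
  epc <- cv[, grepl("^ePC", colnames(cv)), drop = FALSE]
  expect_equal(ncol(epc), 2L)
  expect_lt(abs(crossprod(epc[, 1L], epc[, 2L])), 1e-8)
  # n_hidden = 0 returns only technical covariates
  cv0 <- suppressMessages(build_covariates(info, expr, n_hidden = 0L))
  expect_false(any(grepl("^ePC", colnames(cv0))))
  expect_error(build_covariates(info[1:10, , drop = FALSE], expr),
               "missing")
})

test_that("the cis window is closed at exactly one megabase", {
  genes <- data.frame(gene_id = "G1", chrom = "chr1", tss = 5e6)
  vars <- data.frame(variant_id = c("at_tss", "edge", "outside", "other_chrom"),
                     chrom = c("chr1", "chr1", "chr1", "chr2"),
                     pos = c(5e6, 6e6, 6e6 + 1, 5e6),
                     stringsAsFactors = FALSE)
  cp <- cis_pairs(genes, vars)
  expect_setequal(cp$G1, c("at_tss", "edge"))
})

test_that("both fit paths match the normal-equations oracle", {
  set.seed(62)
  for (rep in 1:20) {
    n <- 30L
    k <- sample(0:4, 1L)
    covars <- if (k > 0) matrix(rnorm(n * k), ncol = k,
                                dimnames = list(NULL, paste0("c", seq_len(k))))
              else matrix(numeric(0), nrow = n, ncol = 0L)
    gpcs <- matrix(rnorm(n * 5L), ncol = 5L,
                   dimnames = list(NULL, paste0("PC", 1:5)))
    v <- rbinom(n, 2L, 0.4)
    if (diff(range(v)) == 0) next
    y <- rnorm(n)
    rec <- fit_global(y, v, covars, gpcs)
    or <- ols_oracle(y, cbind(1, v, covars, gpcs))
    expect_equal(rec$beta, unname(or$coef[2L]), tolerance = 1e-8)
    expect_equal(rec$se, unname(or$se[2L]), tolerance = 1e-8)
    expect_equal(rec$p_value,
                 unname(2 * pt(-abs(or$coef[2L] / or$se[2L]), df = or$df)),
                 tolerance = 1e-8)
    afr <- rbinom(n, 2L, 0.5)
    asn <- rbinom(n, 1L, 0.3)
    rec_l <- fit_local(y, v, covars, afr, asn, rep(0L, n), min_n = 10L)
    or_l <- ols_oracle(y, cbind(1, v, covars, afr, asn))
    expect_equal(rec_l$beta, unname(or_l$coef[2L]), tolerance = 1e-8)
    expect_equal(rec_l$se, unname(or_l$se[2L]), tolerance = 1e-8)
  }
})

test_that("exact relationships and exchangeability hold for single fits", {
  set.seed(63)
  n <- 40L
  v <- rbinom(n, 2L, 0.5)
  none <- matrix(numeric(0), nrow = n, ncol = 0L)
  gpcs0 <- matrix(0, n, 5L, dimnames = list(NULL, paste0("PC", 1:5)))
  rec <- fit_global(2 * v, v, none, gpcs0)
  expect_equal(rec$beta, 2, tolerance = 1e-10)
  expect_lt(rec$se, 1e-10)
  # permutation of samples across all inputs leaves the record unchanged
  y <- rnorm(n)
  gpcs <- matrix(rnorm(n * 5L), ncol = 5L)
  idx <- sample.int(n)
  r1 <- fit_global(y, v, none, gpcs)
  r2 <- fit_global(y[idx], v[idx], none, gpcs[idx, ])
  expect_equal(r1$beta, r2$beta, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  # constant dosage is skipped, not fatal
  expect_true(fit_global(y, rep(1L, n), none, gpcs)$skipped)
})

test_that("unknown-ancestry exclusion and constant-LA reduction work", {
  set.seed(64)
  n <- 50L
  y <- rnorm(n)
  v <- rbinom(n, 2L, 0.4)
  none <- matrix(numeric(0), nrow = n, ncol = 0L)
  unk <- rep(0L, n)
  unk[7L] <- 1L
  rec <- fit_local(y, v, none, rbinom(n, 2L, 0.5), rep(0L, n), unk)
  expect_equal(rec$n_effective, n - 1L)
  # homogeneous locus: LA columns constant, fit reduces to no-ancestry model
  rec_h <- fit_local(y, v, none, rep(0L, n), rep(0L, n), rep(0L, n))
  or <- ols_oracle(y, cbind(1, v))
  expect_equal(rec_h$beta, unname(or$coef[2L]), tolerance = 1e-10)
  expect_equal(rec_h$se, unname(or$se[2L]), tolerance = 1e-10)
  # below the minimum sample size the record is skipped
  many_unk <- rep(1L, n)
  expect_true(fit_local(y, v, none, rep(0L, n), rep(0L, n), many_unk)$skipped)
})

test_that("lead calling keeps exact ties and applies a strict threshold", {
  mk <- function(p, vid) data.frame(gene_id = "G1", variant_id = vid,
                                    method = "LocalAA", beta = 1, se = 1,
                                    t_stat = 1, p_value = p, n_effective = 50L,
                                    skipped = FALSE, stringsAsFactors = FALSE)
  r <- rbind(mk(1e-8, "v1"), mk(1e-7, "v2"))
  ld <- call_leads(r)
  expect_equal(ld$lead_variants[[1L]], "v1")
  expect_true(ld$is_egene)

  r_tie <- rbind(mk(1e-8, "v1"), mk(1e-8, "v2"), mk(1e-7, "v3"))
  expect_equal(call_leads(r_tie)$lead_variants[[1L]], c("v1", "v2"))

  r_edge <- mk(1e-6, "v1")
  expect_false(call_leads(r_edge)$is_egene)

  r_skip <- mk(NA, "v1")
  r_skip$skipped <- TRUE
  expect_message(out <- call_leads(r_skip), "omitted")
  expect_equal(nrow(out), 0L)
})

test_that("LD r-squared is symmetric in allele coding and small under independence", {
  set.seed(65)
  v1 <- rbinom(1000L, 2L, 0.5)
  expect_equal(ld_r2(v1, v1), 1)
  expect_equal(ld_r2(v1, 2L - v1), 1)
  expect_lt(ld_r2(v1, rbinom(1000L, 2L, 0.5)), 0.02)
  expect_true(is.na(ld_r2(v1, rep(1L, 1000L))))
})

test_that("method comparison reproduces the seven-tissue binomial probability", {
  mk_leads <- function(method, egene_by_tissue, lead = "v1") {
    do.call(rbind, lapply(seq_along(egene_by_tissue), function(t) {
      data.frame(gene_id = "G1", method = method,
                 lead_variants = I(list(lead)), lead_p = 1e-8,
                 is_egene = egene_by_tissue[t],
                 tissue = paste0("tissue", t), stringsAsFactors = FALSE)
    }))
  }
  dos <- matrix(rbinom(3L * 40L, 2L, 0.5), nrow = 3L,
                dimnames = list(c("v1", "v2", "v3"), sprintf("S%02d", 1:40)))
  # LocalAA finds an eGene in all 7 tissues, GlobalAA in none
  cmp <- compare_methods(mk_leads("LocalAA", rep(TRUE, 7L)),
                         mk_leads("GlobalAA", rep(FALSE, 7L)), dos)
  expect_equal(cmp$binomial_p, 0.0078125)
  expect_equal(signif(cmp$binomial_p, 2L), 0.0078)
  expect_true(all(cmp$comparison$same_lead))
  # 4 of 7 tissues ahead: tail is exactly 1/2
  cmp2 <- compare_methods(mk_leads("LocalAA", c(rep(TRUE, 4L), rep(FALSE, 3L))),
                          mk_leads("GlobalAA", rep(FALSE, 7L)), dos)
  expect_equal(cmp2$binomial_p, 0.5)
  # different leads require empty intersection and r2 < 1
  ll <- mk_leads("LocalAA", TRUE)[1L, ]
  lg <- mk_leads("GlobalAA", TRUE, lead = "v2")[1L, ]
  cmp3 <- compare_methods(ll, lg, dos)
  expect_false(cmp3$comparison$same_lead)
  expect_true(cmp3$comparison$different_leads)
  # identical variant duplicated under another id: r2 = 1 blocks the call
  dos2 <- dos
  dos2["v2", ] <- dos2["v1", ]
  cmp4 <- compare_methods(ll, lg, dos2)
  expect_false(cmp4$comparison$different_leads)
  lg_bad <- lg
  lg_bad$gene_id <- "G2"
  expect_error(compare_methods(ll, lg_bad, dos), "mismatched gene universes")
})
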