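logsum <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

logdiff <- function(a, b) {
  # log(exp(a) - exp(b)), a >= b
  a + log1p(-exp(b - a))
}

#' Wakefield approximate log Bayes factors
#'
#' Per-variant log Bayes factor for association from an effect estimate and
#' its standard error: `0.5 * (log(V / (V + W)) + z^2 * W / (V + W))` with
#' V = se^2 and prior effect variance W (0.15^2 for quantitative traits,
#' 0.2^2 for case-control). When se is unavailable but z and n are present,
#' V is approximated as 1/n (quant) or 1/(n cf (1 - cf)) (cc) on the
#' standardized scale.
#'
#' @param stats Data.frame with columns beta, se, z (any may be NA per the
#'   fallback), n, case_fraction, trait_type ("quant" or "cc").
#' @param sd_prior Optional prior SD override.
#' @return Numeric vector of log ABFs (NA where neither route applies).
#' @export
wakefield_labf <- function(stats, sd_prior = NULL) {
  type <- if (!is.null(stats$trait_type)) stats$trait_type else "quant"
  w <- if (!is.null(sd_prior)) rep(sd_prior^2, nrow(stats)) else
    ifelse(type == "cc", 0.2^2, 0.15^2)
  se <- stats$se
  z <- if (!is.null(stats$z)) stats$z else stats$beta / stats$se
  v <- se^2
  fallback <- is.na(v) | v <= 0
  if (any(fallback)) {
    cf <- stats$case_fraction
    v_fb <- ifelse(type == "cc", 1 / (stats$n * cf * (1 - cf)), 1 / stats$n)
    v[fallback] <- v_fb[fallback]
  }
  r <- w / (v + w)
  0.5 * (log(1 - r) + z^2 * r)
}

#' Scan a GWAS for seed variants
#'
#' Greedy genome-wide selection of association-signal seeds: repeatedly take
#' the smallest remaining p-value below `p_seed` (ties broken by variant id)
#' as a seed and remove every sub-threshold variant within `window_bp` of it
#' on the same chromosome.
#'
#' @param gwas Data.frame with variant_id, chrom, pos, pvalue.
#' @param p_seed Seed threshold (strict); default 1e-5.
#' @param window_bp Exclusion window half-width; default 1 Mb.
#' @return Data.frame of seeds (variant_id, chrom, pos, pvalue); may be
#'   empty.
#' @export
scan_seeds <- function(gwas, p_seed = 1e-5, window_bp = 1e6) {
  sub <- gwas[!is.na(gwas$pvalue) & gwas$pvalue < p_seed,
              c("variant_id", "chrom", "pos", "pvalue")]
  sub <- sub[order(sub$pvalue, sub$variant_id), , drop = FALSE]
  seeds <- sub[0, , drop = FALSE]
  while (nrow(sub) > 0L) {
    seed <- sub[1L, , drop = FALSE]
    seeds <- rbind(seeds, seed)
    near <- sub$chrom == seed$chrom & abs(sub$pos - seed$pos) <= window_bp
    sub <- sub[!near, , drop = FALSE]
  }
  rownames(seeds) <- NULL
  seeds
}

#' Build a colocalization locus around a GWAS seed
#'
#' A locus is formed only if some eQTL association within `window_bp` of the
#' seed has p below `p_eqtl`. The variant list is the intersection of the
#' GWAS and eQTL summary sets in the window, matched by chromosome and
#' position with alleles harmonized: when ref/alt are swapped between the
#' two sources the GWAS effect and z are sign-flipped; variants with
#' irreconcilable alleles are dropped with a notice.
#'
#' @param seed One-row data.frame from [scan_seeds()].
#' @param gwas GWAS summary table (variant_id, chrom, pos, ref, alt, beta,
#'   se, z, pvalue, n, case_fraction, trait_type).
#' @param eqtl eQTL summary table for one gene and method with the same
#'   columns (p-value column may be named p_value or pvalue).
#' @param p_eqtl eQTL gate (strict); default 1e-4.
#' @param window_bp Window half-width; default 1 Mb.
#' @return An object of class `coloc_locus` (list: seed_variant, variants,
#'   gwas, eqtl) or NULL when the eQTL gate fails or the intersection is
#'   empty.
#' @export
build_locus <- function(seed, gwas, eqtl, p_eqtl = 1e-4, window_bp = 1e6) {
  if (is.null(eqtl$pvalue)) eqtl$pvalue <- eqtl$p_value
  ew <- eqtl[eqtl$chrom == seed$chrom &
               abs(eqtl$pos - seed$pos) <= window_bp, , drop = FALSE]
  if (nrow(ew) == 0L || min(ew$pvalue, na.rm = TRUE) >= p_eqtl) return(NULL)
  gw <- gwas[gwas$chrom == seed$chrom &
               abs(gwas$pos - seed$pos) <= window_bp, , drop = FALSE]
  key_g <- paste(gw$chrom, gw$pos)
  key_e <- paste(ew$chrom, ew$pos)
  common <- intersect(key_g, key_e)
  gw <- gw[match(common, key_g), , drop = FALSE]
  ew <- ew[match(common, key_e), , drop = FALSE]
  same <- gw$ref == ew$ref & gw$alt == ew$alt
  swapped <- gw$ref == ew$alt & gw$alt == ew$ref
  bad <- !same & !swapped
  if (any(bad)) {
    message("dropping ", sum(bad), " variant(s) with unresolvable alleles")
    gw <- gw[!bad, , drop = FALSE]
    ew <- ew[!bad, , drop = FALSE]
    swapped <- swapped[!bad]
  }
  if (any(swapped)) {
    gw$beta[swapped] <- -gw$beta[swapped]
    if (!is.null(gw$z)) gw$z[swapped] <- -gw$z[swapped]
    gw$ref <- ew$ref
    gw$alt <- ew$alt
  }
  if (nrow(gw) == 0L) return(NULL)
  structure(list(seed_variant = seed$variant_id,
                 variants = ew$variant_id, gwas = gw, eqtl = ew),
            class = "coloc_locus")
}

#' COLOC posterior probabilities PP0-PP4
#'
#' Enumerates the five sharing hypotheses over single-variant causal
#' configurations using Wakefield log ABFs for both traits with priors p1,
#' p2 (single-trait causality) and p12 (shared causality), and returns the
#' normalized posterior of each hypothesis.
#'
#' @param locus A `coloc_locus` from [build_locus()].
#' @param p1,p2,p12 Prior probabilities; defaults 1e-4, 1e-4, 1e-5.
#' @return Named numeric vector PP0..PP4 summing to 1.
#' @export
coloc_pp <- function(locus, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  gw <- locus$gwas
  ew <- locus$eqtl
  ok <- !is.na(gw$se) | !is.na(gw$z)
  bad_se <- (!is.na(gw$se) & gw$se <= 0) | (!is.na(ew$se) & ew$se <= 0)
  if (any(bad_se)) {
    message("dropping ", sum(bad_se), " variant(s) with nonpositive se")
    gw <- gw[!bad_se, , drop = FALSE]
    ew <- ew[!bad_se, , drop = FALSE]
  }
  l1 <- wakefield_labf(gw)
  l2 <- wakefield_labf(ew)
  keep <- is.finite(l1) & is.finite(l2)
  l1 <- l1[keep]
  l2 <- l2[keep]
  if (length(l1) == 0L) stop("no usable variants in locus", call. = FALSE)
  s1 <- logsum(l1)
  s2 <- logsum(l2)
  s12 <- logsum(l1 + l2)
  lh <- c(PP0 = 0,
          PP1 = log(p1) + s1,
          PP2 = log(p2) + s2,
          PP3 = log(p1) + log(p2) +
            if (length(l1) > 1L) logdiff(s1 + s2, s12) else -Inf,
          PP4 = log(p12) + s12)
  pp <- exp(lh - logsum(lh))
  pp / sum(pp)
}

#' Single-causal-variant posterior inclusion probabilities
#'
#' Under the restriction of exactly one causal variant per trait, the
#' per-configuration Bayes factors reduce to per-variant Wakefield ABFs (LD
#' cancels), so the PIP of variant i is its ABF normalized over the locus.
#'
#' @param stats Summary table for one trait (beta, se, z, n, case_fraction,
#'   trait_type).
#' @return PIP vector summing to 1.
#' @export
single_causal_pips <- function(stats) {
  labf <- wakefield_labf(stats)
  if (all(!is.finite(labf)))
    stop("no finite Bayes factors in locus", call. = FALSE)
  labf[!is.finite(labf)] <- -Inf
  pip <- exp(labf - logsum(labf))
  pip / sum(pip)
}

#' Colocalization posterior probability from two PIP vectors
#'
#' `CLPP = 1 - prod_i (1 - PIP_GWAS,i * PIP_eQTL,i)` over the K shared
#' variants.
#'
#' @param pip_gwas,pip_eqtl Aligned PIP vectors of equal length, each summing
#'   to at most 1 (+1e-6).
#' @return CLPP in \[0, 1\].
#' @export
clpp <- function(pip_gwas, pip_eqtl) {
  if (length(pip_gwas) != length(pip_eqtl))
    stop("PIP vectors differ in length", call. = FALSE)
  if (sum(pip_gwas) > 1 + 1e-6 || sum(pip_eqtl) > 1 + 1e-6)
    stop("PIP vectors must each sum to at most 1", call. = FALSE)
  1 - prod(1 - pip_gwas * pip_eqtl)
}

#' Score one locus with both colocalization methods
#'
#' Computes COLOC posteriors, the two single-causal PIP vectors, CLPP, and
#' the threshold calls PP4 > 0.5 and CLPP > 0.01 (both strict).
#'
#' @param locus A `coloc_locus`.
#' @param p1,p2,p12 COLOC priors.
#' @param run_finemap Whether to compute PIPs and CLPP; the staged pipeline
#'   only does so at loci with a COLOC call.
#' @return List of class `coloc_result`: pp, pip_gwas, pip_eqtl, clpp,
#'   coloc_call, finemap_call.
#' @export
score_locus <- function(locus, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                        run_finemap = TRUE) {
  pp <- coloc_pp(locus, p1, p2, p12)
  res <- list(pp = pp, pip_gwas = NULL, pip_eqtl = NULL, clpp = NA_real_,
              coloc_call = unname(pp["PP4"] > 0.5), finemap_call = NA)
  if (run_finemap) {
    res$pip_gwas <- single_causal_pips(locus$gwas)
    res$pip_eqtl <- single_causal_pips(locus$eqtl)
    res$clpp <- clpp(res$pip_gwas, res$pip_eqtl)
    res$finemap_call <- res$clpp > 0.01
  }
  class(res) <- "coloc_result"
  res
}

#' Classify adjustment concordance across scored loci
#'
#' Per locus, applies the calls PP4 > 0.5 (COLOC) and CLPP > 0.01 (FINEMAP
#' stage; only evaluated where the staged pipeline ran it) and flags
#' "discordant-adjustment, concordant-method" loci: exactly one of the two
#' ancestry adjustments passes under BOTH scoring methods.
#'
#' @param scores Data.frame with columns locus_id, adjustment ("LocalAA" /
#'   "GlobalAA"), pp4, clpp (NA where the FINEMAP stage did not run).
#' @return Data.frame per locus: locus_id, coloc/finemap calls per
#'   adjustment, `flagged`, `direction` (the adjustment passing both, or
#'   NA).
#' @export
classify_concordance <- function(scores) {
  scores$coloc_call <- scores$pp4 > 0.5
  scores$finemap_call <- !is.na(scores$clpp) & scores$clpp > 0.01
  parts <- split(scores, scores$locus_id)
  rows <- lapply(parts, function(d) {
    get <- function(adj, col) {
      v <- d[[col]][d$adjustment == adj]
      if (length(v) == 0L) FALSE else v[1L]
    }
    pass_both <- c(LocalAA = get("LocalAA", "coloc_call") &&
                     get("LocalAA", "finemap_call"),
                   GlobalAA = get("GlobalAA", "coloc_call") &&
                     get("GlobalAA", "finemap_call"))
    flagged <- sum(pass_both) == 1L
    data.frame(locus_id = d$locus_id[1L],
               local_coloc = get("LocalAA", "coloc_call"),
               local_finemap = get("LocalAA", "finemap_call"),
               global_coloc = get("GlobalAA", "coloc_call"),
               global_finemap = get("GlobalAA", "finemap_call"),
               flagged = flagged,
               direction = if (flagged) names(pass_both)[pass_both] else
                 NA_character_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
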