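#' Draw population allele frequencies under the Balding-Nichols model
#'
#' For every variant an ancestral frequency p is drawn uniform on (0.05, 0.95)
#' and each population k receives a frequency drawn from
#' Beta(p (1 - F_k) / F_k, (1 - p)(1 - F_k) / F_k), so that
#' E\[p_k\] = p and Var\[p_k\] = p (1 - p) F_k. Variant positions are sampled
#' uniformly without replacement per chromosome and sorted, so they are
#' strictly increasing.
#'
#' @param config A [sim_config()].
#' @return An object of class `ancestral_panel`: a list with `variants`
#'   (data.frame: chrom, pos, ref, alt, variant_id, ancestral_freq) and
#'   `pop_freq` (variants x populations matrix).
#' @export
draw_ancestral_panel <- function(config) {
  validate_sim_config(config)
  pops <- config$populations
  per_chrom <- lapply(seq_len(config$n_chromosomes), function(ci) {
    chrom <- paste0("chr", ci)
    pos <- sort(sample.int(as.integer(config$chrom_length_bp),
                           config$n_variants_per_chrom))
    data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
               stringsAsFactors = FALSE)
  })
  variants <- do.call(rbind, per_chrom)
  variants$variant_id <- paste(variants$chrom, variants$pos,
                               variants$ref, variants$alt, sep = "_")
  n_var <- nrow(variants)
  variants$ancestral_freq <- stats::runif(n_var, 0.05, 0.95)

  pop_freq <- matrix(NA_real_, nrow = n_var, ncol = length(pops),
                     dimnames = list(variants$variant_id, pops))
  p <- variants$ancestral_freq
  for (k in seq_along(pops)) {
    f <- config$fst_per_population[k]
    scale <- (1 - f) / f
    pop_freq[, k] <- stats::rbeta(n_var, p * scale, (1 - p) * scale)
  }
  structure(list(variants = variants, pop_freq = pop_freq,
                 populations = pops),
            class = "ancestral_panel")
}

#' Simulate local-ancestry tracts by a Poisson recombination process
#'
#' Per haplotype and chromosome, breakpoints arrive as a Poisson process with
#' rate g per Morgan over the chromosome's genetic length; each segment's
#' ancestry is drawn independently from the individual's global-ancestry
#' proportions (pool-of-ancestors approximation, no Markov dependence).
#' Genetic positions are mapped to physical ones linearly and adjacent
#' same-ancestry segments are merged.
#'
#' @param config A [sim_config()].
#' @param proportions Numeric matrix (individuals x populations) of
#'   global-ancestry proportions; rows must sum to 1 within 1e-6. Row names,
#'   if absent, default to generated sample ids.
#' @return A data.frame of tracts with columns `sample_id`,
#'   `haplotype_index` (0/1), `chrom`, `start`, `end` (0-based, half-open bp)
#'   and `ancestry`.
#' @export
simulate_tracts <- function(config, proportions) {
  validate_sim_config(config)
  if (is.null(dim(proportions)))
    proportions <- matrix(proportions, nrow = 1)
  if (any(abs(rowSums(proportions) - 1) > 1e-6))
    stop("input error: global-ancestry proportions must sum to 1 per individual",
         call. = FALSE)
  n <- nrow(proportions)
  ids <- rownames(proportions)
  if (is.null(ids)) ids <- sample_ids(n)
  pops <- config$populations
  g <- config$generations_since_admixture
  lm_ <- config$chrom_length_morgans
  lbp <- config$chrom_length_bp

  out <- vector("list", n * 2L * config$n_chromosomes)
  slot <- 1L
  for (i in seq_len(n)) {
    pr <- proportions[i, ]
    for (h in 0:1) {
      for (ci in seq_len(config$n_chromosomes)) {
        nb <- stats::rpois(1L, g * lm_)
        bnd <- c(0, sort(stats::runif(nb, 0, lm_)), lm_)
        bp <- round(bnd / lm_ * lbp)
        anc <- sample(pops, length(bnd) - 1L, replace = TRUE, prob = pr)
        keep <- diff(bp) > 0
        starts <- bp[-length(bp)][keep]
        ends <- bp[-1L][keep]
        anc <- anc[keep]
        if (length(anc) == 0L) next
        r <- rle(anc)
        last <- cumsum(r$lengths)
        first <- c(1L, utils::head(last, -1L) + 1L)
        out[[slot]] <- data.frame(
          sample_id = ids[i], haplotype_index = h,
          chrom = paste0("chr", ci),
          start = starts[first], end = ends[last],
          ancestry = r$values, stringsAsFactors = FALSE)
        slot <- slot + 1L
      }
    }
  }
  do.call(rbind, out[seq_len(slot - 1L)])
}

# Ancestry label of the tract covering each (1-based) position of one
# haplotype on one chromosome; NA where no tract covers.
tract_lookup <- function(starts, ends, labels, pos) {
  p0 <- pos - 1L                      # BED half-open, 0-based
  idx <- findInterval(p0, starts)
  lab <- rep(NA_character_, length(pos))
  ok <- idx >= 1L
  ok[ok] <- p0[ok] < ends[idx[ok]]
  lab[ok] <- labels[idx[ok]]
  lab
}

#' Draw phased haplotypes conditional on local-ancestry tracts
#'
#' The allele at a variant on a haplotype is Bernoulli with the frequency of
#' the population whose tract covers the variant.
#'
#' @param panel An [draw_ancestral_panel()] result.
#' @param tracts Tract data.frame as produced by [simulate_tracts()]; every
#'   variant position must be covered by exactly one tract per haplotype.
#' @return A list with `haplotypes` (variants x 2n binary matrix, columns
#'   `<sample>.0`, `<sample>.1`), `sample_ids`, and `hap_ancestry` (variants x
#'   2n character matrix of true per-allele ancestries).
#' @export
simulate_genotypes <- function(panel, tracts) {
  stopifnot(inherits(panel, "ancestral_panel"))
  ids <- unique(tracts$sample_id)
  v <- panel$variants
  n_var <- nrow(v)
  hap_names <- as.vector(t(outer(ids, 0:1, paste, sep = ".")))
  haps <- matrix(0L, nrow = n_var, ncol = length(hap_names),
                 dimnames = list(v$variant_id, hap_names))
  anc_m <- matrix(NA_character_, nrow = n_var, ncol = length(hap_names),
                  dimnames = list(v$variant_id, hap_names))
  split_tr <- split(tracts, list(tracts$sample_id, tracts$haplotype_index,
                                 tracts$chrom), drop = TRUE)
  by_chrom <- split(seq_len(n_var), v$chrom)
  for (id in ids) {
    for (h in 0:1) {
      col <- paste(id, h, sep = ".")
      for (chrom in names(by_chrom)) {
        rows <- by_chrom[[chrom]]
        tr <- split_tr[[paste(id, h, chrom, sep = ".")]]
        if (is.null(tr))
          stop("internal consistency error: no tracts for ", id,
               " haplotype ", h, " on ", chrom, call. = FALSE)
        tr <- tr[order(tr$start), ]
        lab <- tract_lookup(tr$start, tr$end, tr$ancestry, v$pos[rows])
        if (anyNA(lab))
          stop("internal consistency error: uncovered variant position on ",
               chrom, " for ", id, call. = FALSE)
        freq <- panel$pop_freq[cbind(rows, match(lab, panel$populations))]
        haps[rows, col] <- stats::rbinom(length(rows), 1L, freq)
        anc_m[rows, col] <- lab
      }
    }
  }
  list(haplotypes = haps, sample_ids = ids, hap_ancestry = anc_m)
}

#' Dosage matrix from phased haplotypes
#'
#' @param haplotypes Variants x 2n binary matrix with haplotype columns in
#'   `<sample>.0`, `<sample>.1` order.
#' @return Variants x n integer matrix of alternate-allele dosages in
#'   \{0, 1, 2\}.
#' @export
hap_dosages <- function(haplotypes) {
  odd <- seq(1L, ncol(haplotypes), by = 2L)
  d <- haplotypes[, odd, drop = FALSE] + haplotypes[, odd + 1L, drop = FALSE]
  colnames(d) <- sub("\\.0$", "", colnames(haplotypes)[odd])
  d
}

#' Simulate expression with cis-eQTL and ancestry-stratified components
#'
#' For each gene g: `expr = beta * dosage(causal) + gamma_A * AFR_TSS +
#' gamma_S * ASN_TSS + eps`, where AFR_TSS / ASN_TSS are the true
#' local-ancestry allele counts at the gene's TSS, `beta ~ N(0,
#' effect_size_sd^2)` for the eGene fraction of genes (0 otherwise),
#' `gamma ~ N(0, ancestry_expression_effect_sd^2)` and `eps ~ N(0,
#' noise_sd^2)`.
#'
#' @param cohort A cohort as returned by [simulate_cohort()] (or a list with
#'   `panel`, `tracts`, `dosages`, `sample_ids`).
#' @param config A [sim_config()].
#' @param gene_annot Optional gene annotation (gene_id, chrom, tss); if
#'   omitted, `config$n_genes` TSSs are placed uniformly.
#' @return A list with `expression` (genes x samples matrix), `gene_annot`,
#'   and `truth` (gene_id, is_egene, causal_variant, beta, gamma_afr,
#'   gamma_asn).
#' @export
simulate_expression <- function(cohort, config, gene_annot = NULL) {
  validate_sim_config(config)
  v <- cohort$panel$variants
  ids <- cohort$sample_ids
  n <- length(ids)
  if (is.null(gene_annot)) {
    chrom <- paste0("chr", sample.int(config$n_chromosomes, config$n_genes,
                                      replace = TRUE))
    tss <- sample.int(as.integer(config$chrom_length_bp), config$n_genes,
                      replace = TRUE)
    gene_annot <- data.frame(gene_id = sprintf("G%04d", seq_len(config$n_genes)),
                             chrom = chrom, tss = tss,
                             stringsAsFactors = FALSE)
  }
  m <- nrow(gene_annot)
  n_eg <- round(m * config$eqtl_fraction)
  egenes <- sample.int(m, n_eg)

  tss_sites <- data.frame(chrom = gene_annot$chrom, pos = gene_annot$tss,
                          variant_id = gene_annot$gene_id,
                          stringsAsFactors = FALSE)
  la_tss <- la_counts(cohort$tracts, tss_sites, samples = ids)

  expr <- matrix(stats::rnorm(m * n, sd = config$noise_sd), nrow = m,
                 dimnames = list(gene_annot$gene_id, ids))
  truth <- data.frame(gene_id = gene_annot$gene_id, is_egene = FALSE,
                      causal_variant = NA_character_, beta = 0,
                      gamma_afr = 0, gamma_asn = 0, stringsAsFactors = FALSE)
  if (config$ancestry_expression_effect_sd > 0) {
    truth$gamma_afr <- stats::rnorm(m, sd = config$ancestry_expression_effect_sd)
    truth$gamma_asn <- stats::rnorm(m, sd = config$ancestry_expression_effect_sd)
    expr <- expr + truth$gamma_afr * la_tss$afr[gene_annot$gene_id, ids] +
      truth$gamma_asn * la_tss$asn[gene_annot$gene_id, ids]
  }
  for (gi in egenes) {
    cand <- which(v$chrom == gene_annot$chrom[gi] &
                    abs(v$pos - gene_annot$tss[gi]) <= 1e6)
    if (length(cand) == 0L) {
      warning("no variant within 1 Mb of TSS for gene ",
              gene_annot$gene_id[gi], "; emitted with beta = 0")
      next
    }
    cv <- if (length(cand) == 1L) cand else sample(cand, 1L)
    b <- stats::rnorm(1L, sd = config$effect_size_sd)
    truth$is_egene[gi] <- TRUE
    truth$causal_variant[gi] <- v$variant_id[cv]
    truth$beta[gi] <- b
    expr[gi, ] <- expr[gi, ] + b * cohort$dosages[cv, ids]
  }
  list(expression = expr, gene_annot = gene_annot, truth = truth)
}

#' Per-variant marginal association statistics
#'
#' Simple linear regression of a trait on each variant's dosage, vectorized
#' across variants: beta = Sxy/Sxx, se from the residual variance at n - 2
#' degrees of freedom, z = beta/se, two-sided p from the t distribution.
#'
#' @param dosages Variants x samples dosage matrix.
#' @param y Trait vector (length = samples).
#' @return A data.frame (variant_id, beta, se, z, pvalue, n); monomorphic
#'   variants get NA statistics.
#' @export
marginal_stats <- function(dosages, y) {
  n <- length(y)
  stopifnot(ncol(dosages) == n)
  yc <- y - mean(y)
  xm <- rowMeans(dosages)
  sxx <- rowSums(dosages^2) - n * xm^2
  sxy <- as.vector(dosages %*% yc)
  syy <- sum(yc^2)
  beta <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  rss <- syy - beta * sxy
  sigma2 <- pmax(rss, 0) / (n - 2L)
  se <- sqrt(sigma2 / sxx)
  z <- beta / se
  p <- 2 * stats::pt(-abs(z), df = n - 2L)
  data.frame(variant_id = rownames(dosages), beta = beta, se = se, z = z,
             pvalue = p, n = n, stringsAsFactors = FALSE)
}

#' Simulate GWAS summary statistics on an independent cohort
#'
#' A fresh cohort of `gwas_n` individuals is generated from the same ancestral
#' panel and tract machinery as the eQTL cohort. For each eGene a quantitative
#' GWAS trait is built whose causal variant equals the eQTL causal variant for
#' `gwas_shared_fraction` of eGenes and is a different cis-window variant
#' otherwise (no causal variant if the window holds no alternative). Marginal
#' per-variant statistics are computed over the gene's cis window.
#'
#' @param cohort An eQTL cohort from [simulate_cohort()] (carries the panel
#'   and the expression truth).
#' @param config A [sim_config()].
#' @param window_bp Half-width of the cis window around each gene TSS.
#' @return A list with `traits` (data.frame: trait_id, gene_id, shared,
#'   causal_variant), `stats` (named list of per-trait marginal statistics
#'   with chrom/pos/ref/alt columns), and `cohort_dosages` (the GWAS cohort's
#'   dosages, for LD-aware downstream checks).
#' @export
simulate_gwas <- function(cohort, config, window_bp = 1e6) {
  validate_sim_config(config)
  panel <- cohort$panel
  v <- panel$variants
  gcfg <- config
  gcfg$n_individuals <- config$gwas_n
  props <- rdirichlet(config$gwas_n, config$dirichlet_alpha)
  rownames(props) <- sprintf("GW%05d", seq_len(config$gwas_n))
  tr <- simulate_tracts(gcfg, props)
  geno <- simulate_genotypes(panel, tr)
  dos <- hap_dosages(geno$haplotypes)

  truth <- cohort$truth
  eg <- truth[truth$is_egene & !is.na(truth$causal_variant), , drop = FALSE]
  annot <- cohort$gene_annot
  n_eg <- nrow(eg)
  shared <- rep(FALSE, n_eg)
  if (n_eg > 0L) {
    n_sh <- round(n_eg * config$gwas_shared_fraction)
    if (n_sh > 0L) shared[sample.int(n_eg, n_sh)] <- TRUE
  }
  traits <- data.frame(trait_id = paste0("T_", eg$gene_id),
                       gene_id = eg$gene_id, shared = shared,
                       causal_variant = NA_character_,
                       stringsAsFactors = FALSE)
  stats_list <- vector("list", n_eg)
  names(stats_list) <- traits$trait_id
  for (j in seq_len(n_eg)) {
    gi <- match(eg$gene_id[j], annot$gene_id)
    win <- which(v$chrom == annot$chrom[gi] &
                   abs(v$pos - annot$tss[gi]) <= window_bp)
    cv_eqtl <- match(eg$causal_variant[j], v$variant_id)
    if (shared[j]) {
      cv <- cv_eqtl
    } else {
      alt_cand <- setdiff(win, cv_eqtl)
      cv <- if (length(alt_cand) == 0L) NA_integer_ else
        if (length(alt_cand) == 1L) alt_cand else sample(alt_cand, 1L)
    }
    y <- stats::rnorm(config$gwas_n)
    if (!is.na(cv)) {
      b <- stats::rnorm(1L, sd = config$effect_size_sd)
      y <- y + b * dos[cv, ]
      traits$causal_variant[j] <- v$variant_id[cv]
    }
    st <- marginal_stats(dos[win, , drop = FALSE], y)
    st <- cbind(st, v[win, c("chrom", "pos", "ref", "alt")])
    st$case_fraction <- NA_real_
    st$trait_type <- "quant"
    stats_list[[j]] <- st
  }
  list(traits = traits, stats = stats_list, cohort_dosages = dos)
}

#' Generate a complete synthetic admixed cohort
#'
#' Runs the full generator under the configuration's seed: ancestral panel,
#' Dirichlet global-ancestry proportions, Poisson-recombination tracts, phased
#' haplotypes, dosages, realized global-ancestry fractions, and one expression
#' draw per tissue.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_cohort`: list with `config`, `panel`,
#'   `proportions` (Dirichlet draws), `tracts`, `haplotypes`, `hap_ancestry`,
#'   `dosages`, `sample_ids`, `true_global_ancestry` (realized tract-length
#'   fractions, individuals x populations), `gene_annot`, `expression` (list
#'   of genes x samples matrices, one per tissue), `truth` (per-tissue list).
#'   For convenience `$truth` of tissue 1 is also exposed at the top level.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  panel <- draw_ancestral_panel(config)
  props <- rdirichlet(config$n_individuals, config$dirichlet_alpha)
  rownames(props) <- sample_ids(config$n_individuals)
  colnames(props) <- config$populations
  tracts <- simulate_tracts(config, props)
  geno <- simulate_genotypes(panel, tracts)
  dos <- hap_dosages(geno$haplotypes)
  ga <- global_fractions(tracts)
  ga_m <- as.matrix(ga[, config$populations])
  rownames(ga_m) <- ga$sample_id
  ga_m <- ga_m[geno$sample_ids, , drop = FALSE]

  cohort <- list(config = config, panel = panel, proportions = props,
                 tracts = tracts, haplotypes = geno$haplotypes,
                 hap_ancestry = geno$hap_ancestry, dosages = dos,
                 sample_ids = geno$sample_ids, true_global_ancestry = ga_m)
  expr_list <- vector("list", config$n_tissues)
  truth_list <- vector("list", config$n_tissues)
  gene_annot <- NULL
  for (t in seq_len(config$n_tissues)) {
    ex <- simulate_expression(cohort, config, gene_annot = gene_annot)
    gene_annot <- ex$gene_annot
    expr_list[[t]] <- ex$expression
    truth_list[[t]] <- ex$truth
  }
  names(expr_list) <- names(truth_list) <- paste0("tissue", seq_len(config$n_tissues))
  cohort$gene_annot <- gene_annot
  cohort$expression <- expr_list
  cohort$truth_by_tissue <- truth_list
  cohort$truth <- truth_list[[1L]]
  class(cohort) <- "sim_cohort"
  cohort
}

#' Emit per-site ancestry "posteriors" from simulated truth
#'
#' Produces the per-site posterior table an ancestry-inference tool would
#' emit, so the thresholding path of the tract post-processor can be
#' exercised. With `blur_rate = 0` every site carries posterior 1.0 on the
#' true population; with `blur_rate > 0` a fraction of sites get their true
#' population's posterior drawn uniform on (1/3, `blur_max`), the remainder
#' split equally, so sites with `blur_max < threshold` become "unknown"
#' downstream.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param positions Data.frame (chrom, pos) of sites to emit; defaults to the
#'   cohort's variant positions.
#' @param blur_rate Fraction of sites blurred.
#' @param blur_max Upper bound of the blurred true-population posterior.
#' @return Long data.frame: sample_id, haplotype_index, chrom, pos, p_EUR,
#'   p_AFR, p_ASN.
#' @export
emit_site_posteriors <- function(cohort, positions = NULL, blur_rate = 0,
                                 blur_max = 0.85) {
  pops <- cohort$config$populations
  v <- cohort$panel$variants
  if (is.null(positions)) positions <- v[, c("chrom", "pos")]
  rows <- match(paste(positions$chrom, positions$pos),
                paste(v$chrom, v$pos))
  if (anyNA(rows)) stop("positions must be cohort variant positions")
  hap_cols <- colnames(cohort$hap_ancestry)
  out <- vector("list", length(hap_cols))
  for (j in seq_along(hap_cols)) {
    lab <- cohort$hap_ancestry[rows, hap_cols[j]]
    k <- length(lab)
    p_true <- rep(1, k)
    if (blur_rate > 0) {
      blur <- stats::runif(k) < blur_rate
      p_true[blur] <- stats::runif(sum(blur), 1 / 3, blur_max)
    }
    post <- matrix((1 - p_true) / 2, nrow = k, ncol = 3,
                   dimnames = list(NULL, pops))
    post[cbind(seq_len(k), match(lab, pops))] <- p_true
    sid <- sub("\\.[01]$", "", hap_cols[j])
    hidx <- as.integer(sub("^.*\\.", "", hap_cols[j]))
    out[[j]] <- data.frame(sample_id = sid, haplotype_index = hidx,
                           chrom = positions$chrom, pos = positions$pos,
                           p_EUR = post[, "EUR"], p_AFR = post[, "AFR"],
                           p_ASN = post[, "ASN"], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
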