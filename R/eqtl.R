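#' Build the technical covariate matrix for eQTL mapping
#'
#' One-hot encodes categorical sample covariates (e.g. sex, sequencing
#' platform, library construction protocol), drops constant columns with a
#' notice, and appends the top `n_hidden` expression principal components as
#' stand-ins for hidden confounders.
#'
#' @param sample_info Data.frame of per-sample covariates; row names are
#'   sample ids. NAs are an error.
#' @param expression Genes x samples matrix used for the expression PCs.
#' @param n_hidden Number of expression PCs to append; default 3.
#' @return Samples x covariates numeric matrix (possibly zero columns).
#' @export
build_covariates <- function(sample_info, expression, n_hidden = 3L) {
  samples <- colnames(expression)
  if (!is.null(sample_info) && ncol(sample_info) > 0L) {
    if (!all(samples %in% rownames(sample_info)))
      stop("covariates missing for samples: ",
           paste(setdiff(samples, rownames(sample_info)), collapse = ", "),
           call. = FALSE)
    si <- sample_info[samples, , drop = FALSE]
    if (anyNA(si))
      stop("covariates missing (NA) for some samples", call. = FALSE)
    si[] <- lapply(si, function(col) if (is.character(col)) factor(col) else col)
    single <- vapply(si, function(col) length(unique(col)) < 2L, logical(1))
    if (any(single)) {
      message("dropping constant covariate column(s): ",
              paste(names(si)[single], collapse = ", "))
      si <- si[, !single, drop = FALSE]
    }
    mm <- if (ncol(si) > 0L)
      stats::model.matrix(~ ., data = si)[, -1L, drop = FALSE]
    else matrix(numeric(0), nrow = length(samples), ncol = 0L)
  } else {
    mm <- matrix(numeric(0), nrow = length(samples), ncol = 0L)
    rownames(mm) <- samples
  }
  dc <- drop_constant_cols(mm)
  if (length(dc$dropped) > 0L)
    message("dropping constant covariate column(s): ",
            paste(dc$dropped, collapse = ", "))
  covs <- dc$x
  if (n_hidden > 0L) {
    xc <- scale(t(expression), center = TRUE, scale = FALSE)  # samples x genes
    sv <- svd(xc, nu = n_hidden, nv = 0)
    epc <- sv$u %*% diag(sv$d[seq_len(n_hidden)], n_hidden)
    colnames(epc) <- paste0("ePC", seq_len(n_hidden))
    covs <- cbind(covs, epc)
  }
  rownames(covs) <- samples
  covs
}

#' Enumerate cis gene-variant pairs
#'
#' A variant is cis to a gene if it lies on the same chromosome within
#' `window_bp` of the TSS (closed window: a variant exactly at TSS +/-
#' `window_bp` is included).
#'
#' @param gene_annot Data.frame (gene_id, chrom, tss).
#' @param variants Data.frame (variant_id, chrom, pos).
#' @param window_bp Window half-width; default 1 Mb.
#' @return Named list: gene_id -> character vector of cis variant ids (empty
#'   for genes with no cis variant, with a notice).
#' @export
cis_pairs <- function(gene_annot, variants, window_bp = 1e6) {
  out <- lapply(seq_len(nrow(gene_annot)), function(gi) {
    hit <- variants$chrom == gene_annot$chrom[gi] &
      abs(variants$pos - gene_annot$tss[gi]) <= window_bp
    variants$variant_id[hit]
  })
  names(out) <- gene_annot$gene_id
  empty <- names(out)[lengths(out) == 0L]
  if (length(empty) > 0L)
    message(length(empty), " gene(s) with no cis variants: ",
            paste(utils::head(empty, 5L), collapse = ", "),
            if (length(empty) > 5L) " ..." else "")
  out
}

eqtl_record <- function(gene_id, variant_id, method, fit = NULL, n = NA_integer_) {
  if (is.null(fit)) {
    return(data.frame(gene_id = gene_id, variant_id = variant_id,
                      method = method, beta = NA_real_, se = NA_real_,
                      t_stat = NA_real_, p_value = NA_real_,
                      n_effective = n, skipped = TRUE,
                      stringsAsFactors = FALSE))
  }
  b <- fit$coef[["v"]]
  s <- fit$se[["v"]]
  t <- b / s
  data.frame(gene_id = gene_id, variant_id = variant_id, method = method,
             beta = b, se = s, t_stat = t,
             p_value = 2 * stats::pt(-abs(t), df = fit$df),
             n_effective = n, skipped = FALSE, stringsAsFactors = FALSE)
}

#' Single gene-variant association with global-ancestry adjustment
#'
#' OLS of expression on an intercept, the variant dosage, the technical
#' covariates and the first five genotype PCs. The association p-value is the
#' two-sided t-tail for the dosage coefficient at n - rank degrees of
#' freedom.
#'
#' @param y Expression vector.
#' @param v Dosage vector in \{0, 1, 2\}.
#' @param covars Technical covariate matrix (may have zero columns).
#' @param gpcs Samples x 5 genotype PC score matrix.
#' @param gene_id,variant_id Identifiers carried into the record.
#' @return One-row association record; a constant dosage yields a record
#'   flagged `skipped` with NA statistics.
#' @export
fit_global <- function(y, v, covars, gpcs, gene_id = "gene",
                       variant_id = "variant") {
  if (diff(range(v)) == 0)
    return(eqtl_record(gene_id, variant_id, "GlobalAA", n = length(y)))
  blocks <- drop_constant_cols(cbind(covars, gpcs))$x
  X <- cbind(`(Intercept)` = 1, v = v, blocks)
  fit <- ols_stats(y, X)
  eqtl_record(gene_id, variant_id, "GlobalAA", fit, n = length(y))
}

#' Single gene-variant association with local-ancestry adjustment
#'
#' Samples with any unknown-ancestry allele at the variant are excluded, then
#' expression is regressed on an intercept, the dosage, the technical
#' covariates, and the AFR and ASN local-ancestry allele counts at the
#' variant. Ancestry or covariate columns that are constant after the
#' exclusion are dropped, so the covariate matrix is rebuilt per variant.
#'
#' @param y Expression vector.
#' @param v Dosage vector.
#' @param covars Technical covariate matrix.
#' @param la_afr,la_asn,la_unk Per-sample AFR / ASN / unknown allele counts at
#'   the variant.
#' @param min_n Minimum post-exclusion sample size; below it the record is
#'   flagged skipped. Default 30.
#' @param gene_id,variant_id Identifiers carried into the record.
#' @return One-row association record with `n_effective` reflecting the
#'   exclusions.
#' @export
fit_local <- function(y, v, covars, la_afr, la_asn, la_unk, min_n = 30L,
                      gene_id = "gene", variant_id = "variant") {
  keep <- la_unk == 0L
  n_eff <- sum(keep)
  if (n_eff < min_n)
    return(eqtl_record(gene_id, variant_id, "LocalAA", n = n_eff))
  y <- y[keep]
  v <- v[keep]
  if (diff(range(v)) == 0)
    return(eqtl_record(gene_id, variant_id, "LocalAA", n = n_eff))
  la <- cbind(AFR = la_afr[keep], ASN = la_asn[keep])
  blocks <- drop_constant_cols(cbind(covars[keep, , drop = FALSE], la))$x
  X <- cbind(`(Intercept)` = 1, v = v, blocks)
  fit <- ols_stats(y, X)
  eqtl_record(gene_id, variant_id, "LocalAA", fit, n = n_eff)
}

fit_unadjusted <- function(y, v, covars, gene_id = "gene",
                           variant_id = "variant") {
  if (diff(range(v)) == 0)
    return(eqtl_record(gene_id, variant_id, "Unadjusted", n = length(y)))
  X <- cbind(`(Intercept)` = 1, v = v, drop_constant_cols(covars)$x)
  fit <- ols_stats(y, X)
  eqtl_record(gene_id, variant_id, "Unadjusted", fit, n = length(y))
}

#' Map cis-eQTLs across genes with a chosen ancestry adjustment
#'
#' Loops [fit_global()], [fit_local()] or an unadjusted fit (technical
#' covariates only) over every cis gene-variant pair.
#'
#' @param expression Genes x samples matrix.
#' @param dosages Variants x samples dosage matrix.
#' @param cis Named list gene_id -> cis variant ids, from [cis_pairs()].
#' @param covars Technical covariate matrix (samples x k).
#' @param gpcs Genotype PC scores (required for `method = "global"`).
#' @param la [la_counts()] result at the tested variants (required for
#'   `method = "local"`).
#' @param method One of "global", "local", "unadjusted".
#' @param min_n Minimum post-exclusion sample size for the local fit.
#' @return Data.frame of association records.
#' @export
map_eqtls <- function(expression, dosages, cis, covars = NULL, gpcs = NULL,
                      la = NULL, method = c("global", "local", "unadjusted"),
                      min_n = 30L) {
  method <- match.arg(method)
  samples <- colnames(expression)
  if (is.null(covars))
    covars <- matrix(numeric(0), nrow = length(samples), ncol = 0L,
                     dimnames = list(samples, NULL))
  covars <- covars[samples, , drop = FALSE]
  if (method == "global") {
    gpcs <- gpcs[samples, seq_len(min(5L, ncol(gpcs))), drop = FALSE]
  }
  recs <- vector("list", sum(lengths(cis)))
  slot <- 1L
  for (g in names(cis)) {
    y <- expression[g, samples]
    for (vid in cis[[g]]) {
      v <- dosages[vid, samples]
      recs[[slot]] <- switch(
        method,
        global = fit_global(y, v, covars, gpcs, g, vid),
        local = fit_local(y, v, covars,
                          la$afr[vid, samples], la$asn[vid, samples],
                          la$unk[vid, samples], min_n, g, vid),
        unadjusted = fit_unadjusted(y, v, covars, g, vid))
      slot <- slot + 1L
    }
  }
  do.call(rbind, recs[seq_len(slot - 1L)])
}

#' Call lead eVariants per gene
#'
#' The lead set is every variant attaining the gene's smallest association
#' p-value (ties kept, compared on exact stored values); a gene is an eGene
#' if the lead p-value is strictly below `threshold`.
#'
#' @param records Association records from [map_eqtls()].
#' @param threshold Nominal significance threshold; default 1e-6.
#' @return Data.frame: gene_id, method, lead_variants (list column), lead_p,
#'   is_egene. Genes whose records are all skipped are omitted with a notice.
#' @export
call_leads <- function(records, threshold = 1e-6) {
  ok <- records[!records$skipped & !is.na(records$p_value), , drop = FALSE]
  dropped <- setdiff(unique(records$gene_id), unique(ok$gene_id))
  if (length(dropped) > 0L)
    message(length(dropped), " gene(s) omitted: all records skipped")
  if (nrow(ok) == 0L)
    return(data.frame(gene_id = character(), method = character(),
                      lead_variants = I(list()), lead_p = numeric(),
                      is_egene = logical(), stringsAsFactors = FALSE))
  parts <- split(ok, ok$gene_id)
  rows <- lapply(parts, function(d) {
    pmin_ <- min(d$p_value)
    leads <- sort(d$variant_id[d$p_value == pmin_])
    data.frame(gene_id = d$gene_id[1L], method = d$method[1L],
               lead_variants = I(list(leads)), lead_p = pmin_,
               is_egene = pmin_ < threshold, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Linkage disequilibrium between two variants
#'
#' Squared Pearson correlation of dosages; NA when either vector is constant.
#'
#' @param v1,v2 Dosage vectors over the same samples.
#' @return r-squared in \[0, 1\] or NA.
#' @export
ld_r2 <- function(v1, v2) {
  if (diff(range(v1)) == 0 || diff(range(v2)) == 0) return(NA_real_)
  stats::cor(v1, v2)^2
}

#' Compare lead eVariants and eGene yield between the two adjustments
#'
#' Per gene (and tissue, when a `tissue` column is present), classifies the
#' LocalAA and GlobalAA lead sets as shared or different. Leads are
#' "different" only if (1) the two lead sets do not intersect and (2) the LD
#' r-squared between the pair of lead variants (lexicographically smallest of
#' each set) is below 1.0. Per-tissue eGene counts are tabulated, and a
#' one-sided binomial tail probability P(X >= k | n tissues, 1/2) is computed
#' for the k tissues where LocalAA found more eGenes.
#'
#' @param leads_local,leads_global Lead tables from [call_leads()] (optionally
#'   with a `tissue` column); both must cover the same gene universe.
#' @param dosages Variants x samples dosage matrix for the LD computation.
#' @return List: `comparison` (gene_id \[, tissue\], same_lead, ld_r2,
#'   different_leads), `egene_counts` (tissue, n_local, n_global),
#'   `binomial_p`.
#' @export
compare_methods <- function(leads_local, leads_global, dosages) {
  if (is.null(leads_local$tissue)) leads_local$tissue <- "tissue1"
  if (is.null(leads_global$tissue)) leads_global$tissue <- "tissue1"
  kl <- paste(leads_local$tissue, leads_local$gene_id)
  kg <- paste(leads_global$tissue, leads_global$gene_id)
  if (!setequal(kl, kg)) {
    diff_ <- c(setdiff(kl, kg), setdiff(kg, kl))
    stop("mismatched gene universes between methods: ",
         paste(utils::head(diff_, 10L), collapse = ", "), call. = FALSE)
  }
  leads_global <- leads_global[match(kl, kg), , drop = FALSE]
  n <- nrow(leads_local)
  same <- logical(n)
  r2 <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    a <- leads_local$lead_variants[[i]]
    b <- leads_global$lead_variants[[i]]
    same[i] <- length(intersect(a, b)) > 0L
    if (!same[i])
      r2[i] <- ld_r2(dosages[min(a), ], dosages[min(b), ])
  }
  different <- !same & !is.na(r2) & r2 < 1.0
  comparison <- data.frame(gene_id = leads_local$gene_id,
                           tissue = leads_local$tissue,
                           same_lead = same, ld_r2 = r2,
                           different_leads = different,
                           stringsAsFactors = FALSE)
  tissues <- sort(unique(leads_local$tissue))
  counts <- data.frame(
    tissue = tissues,
    n_local = vapply(tissues, function(t)
      sum(leads_local$is_egene[leads_local$tissue == t]), integer(1)),
    n_global = vapply(tissues, function(t)
      sum(leads_global$is_egene[leads_global$tissue == t]), integer(1)),
    stringsAsFactors = FALSE)
  k <- sum(counts$n_local > counts$n_global)
  list(comparison = comparison, egene_counts = counts,
       binomial_p = binomial_tail(k, nrow(counts)))
}

#' One-sided binomial tail probability
#'
#' P(X >= k) for X ~ Binomial(n, 1/2): the probability that at least k of n
#' tissues favor one method if neither is better. At k = n = 7 this is
#' 0.5^7 = 0.0078125.
#'
#' @param k Observed number of favorable tissues.
#' @param n Number of tissues.
#' @return Tail probability.
#' @export
binomial_tail <- function(k, n) {
  stats::pbinom(k - 1L, size = n, prob = 0.5, lower.tail = FALSE)
}
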