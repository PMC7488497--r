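#' Approximate local ancestry for homogeneous-population samples
#'
#' Samples known to be ancestrally homogeneous European are assigned two
#' European alleles at every queried locus, so the confounding screen can
#' cover a full cohort when tracts were only inferred for its admixed
#' subset.
#'
#' @param samples Homogeneous sample ids.
#' @param variant_ids Loci to emit counts for.
#' @param inferred_samples Sample ids that already carry inferred tracts;
#'   overlap is an error.
#' @return A [la_counts()]-style list of four loci x samples matrices.
#' @export
approximate_homogeneous <- function(samples, variant_ids,
                                    inferred_samples = character()) {
  overlap <- intersect(samples, inferred_samples)
  if (length(overlap) > 0L)
    stop("samples have inferred tracts and cannot be approximated: ",
         paste(utils::head(overlap, 5L), collapse = ", "), call. = FALSE)
  mk <- function(fill) matrix(fill, nrow = length(variant_ids),
                              ncol = length(samples),
                              dimnames = list(variant_ids, samples))
  list(eur = mk(2L), afr = mk(0L), asn = mk(0L), unk = mk(0L))
}

# Column-bind two la_counts structures over disjoint sample sets.
merge_la_counts <- function(a, b) {
  stopifnot(identical(rownames(a$eur), rownames(b$eur)))
  lapply(stats::setNames(nm = names(a)), function(k) cbind(a[[k]], b[[k]]))
}

#' Variance in a variant's genotype explained by local ancestry
#'
#' R-squared from OLS of the minor-allele dosage on an intercept plus the
#' AFR and ASN local-ancestry allele counts, with confounding flags at
#' R-squared strictly above 0.7 and 0.9 (the R-squared itself is invariant
#' to whether the dosage counts minor or alternate alleles).
#'
#' @param v Dosage vector over the analysis samples.
#' @param la_afr,la_asn Allele-count vectors aligned with `v`.
#' @param variant_id,scope Identifiers carried into the record (`scope` is
#'   "all_samples" or a tissue label).
#' @return One-row data.frame: variant_id, scope, r_squared, n, flag_07,
#'   flag_09, skipped. A constant genotype yields a skipped record.
#' @export
genotype_la_r2 <- function(v, la_afr, la_asn, variant_id = "variant",
                           scope = "all_samples") {
  n <- length(v)
  if (diff(range(v)) == 0)
    return(data.frame(variant_id = variant_id, scope = scope,
                      r_squared = NA_real_, n = n, flag_07 = FALSE,
                      flag_09 = FALSE, skipped = TRUE,
                      stringsAsFactors = FALSE))
  # orient to minor allele within the analysis subset
  if (mean(v) > 1) v <- 2 - v
  dc <- drop_constant_cols(cbind(AFR = la_afr, ASN = la_asn))
  r2 <- if (ncol(dc$x) == 0L) 0 else
    ols_stats(v, cbind(`(Intercept)` = 1, dc$x))$r_squared
  data.frame(variant_id = variant_id, scope = scope, r_squared = r2, n = n,
             flag_07 = r2 > 0.7, flag_09 = r2 > 0.9, skipped = FALSE,
             stringsAsFactors = FALSE)
}

#' Screen eVariants for genotype-local-ancestry confounding
#'
#' Runs [genotype_la_r2()] in two scopes: once per unique eVariant over all
#' supplied samples, and once per (eVariant, tissue) over the samples with
#' expression in that tissue.
#'
#' @param leads Lead table(s) from [call_leads()] with a `tissue` column (or
#'   a list of per-tissue tables); eVariants are the union of lead sets of
#'   significant eGenes.
#' @param dosages Variants x samples dosage matrix (full cohort).
#' @param la [la_counts()]-style list covering the same variants and
#'   samples.
#' @param tissue_samples Named list tissue -> sample ids.
#' @return List: `all_samples` (one record per eVariant), `by_tissue` (one
#'   per eVariant-tissue), `flagged` (records with R-squared > 0.7).
#' @export
screen_confounding <- function(leads, dosages, la, tissue_samples) {
  if (is.data.frame(leads)) leads <- list(leads)
  per_tissue <- list()
  for (tb in leads) {
    if (is.null(tb$tissue)) tb$tissue <- "tissue1"
    sig <- tb[tb$is_egene, , drop = FALSE]
    for (t in unique(sig$tissue)) {
      vs <- sort(unique(unlist(sig$lead_variants[sig$tissue == t])))
      per_tissue[[t]] <- union(per_tissue[[t]], vs)
    }
  }
  all_vars <- sort(unique(unlist(per_tissue)))
  all_samp <- colnames(dosages)
  all_recs <- lapply(all_vars, function(vid)
    genotype_la_r2(dosages[vid, all_samp], la$afr[vid, all_samp],
                   la$asn[vid, all_samp], vid, "all_samples"))
  tis_recs <- list()
  for (t in names(per_tissue)) {
    ts <- tissue_samples[[t]]
    for (vid in per_tissue[[t]]) {
      tis_recs[[paste(t, vid)]] <-
        genotype_la_r2(dosages[vid, ts], la$afr[vid, ts], la$asn[vid, ts],
                       vid, t)
    }
  }
  empty <- genotype_la_r2(c(0, 1), c(0, 0), c(0, 0))[0, ]
  all_df <- if (length(all_recs)) do.call(rbind, all_recs) else empty
  tis_df <- if (length(tis_recs)) do.call(rbind, tis_recs) else empty
  rownames(all_df) <- rownames(tis_df) <- NULL
  both <- rbind(all_df, tis_df)
  list(all_samples = all_df, by_tissue = tis_df,
       flagged = both[!both$skipped & both$flag_07, , drop = FALSE])
}
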