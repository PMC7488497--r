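#' Threshold per-site ancestry posteriors into hard labels
#'
#' A phased allele is assigned to the population with the highest posterior
#' only if that posterior is at least `threshold` (inclusive); otherwise its
#' local ancestry is "UNK".
#'
#' @param posteriors Data.frame with columns sample_id, haplotype_index,
#'   chrom, pos, p_EUR, p_AFR, p_ASN.
#' @param threshold Assignment threshold; default 0.9.
#' @return The input with an `ancestry` column (EUR/AFR/ASN/UNK) appended.
#' @export
assign_sites <- function(posteriors, threshold = 0.9) {
  pm <- as.matrix(posteriors[, c("p_EUR", "p_AFR", "p_ASN")])
  bad <- which(abs(rowSums(pm) - 1) > 1e-3)
  if (length(bad) > 0L)
    stop("input error: posteriors do not sum to 1 at site ",
         posteriors$chrom[bad[1L]], ":", posteriors$pos[bad[1L]],
         " (sample ", posteriors$sample_id[bad[1L]], ")", call. = FALSE)
  best <- max.col(pm, ties.method = "first")
  lab <- c("EUR", "AFR", "ASN")[best]
  lab[pm[cbind(seq_len(nrow(pm)), best)] < threshold] <- "UNK"
  posteriors$ancestry <- lab
  posteriors
}

#' Collapse per-site ancestry labels into haplotype tracts
#'
#' Run-length encodes consecutive identical labels per sample, haplotype and
#' chromosome. Site positions are 1-based (VCF convention); tracts are
#' emitted 0-based half-open (BED convention): a run from the site at
#' position a to the site at position b becomes the tract \[a - 1, b).
#' Runs of "UNK" become UNK tracts.
#'
#' @param labels Data.frame with columns sample_id, haplotype_index, chrom,
#'   pos, ancestry, sorted by position within each haplotype and chromosome.
#' @return Tract data.frame (sample_id, haplotype_index, chrom, start, end,
#'   ancestry).
#' @export
collapse_tracts <- function(labels) {
  if (nrow(labels) == 0L)
    return(data.frame(sample_id = character(), haplotype_index = integer(),
                      chrom = character(), start = numeric(), end = numeric(),
                      ancestry = character(), stringsAsFactors = FALSE))
  key <- interaction(labels$sample_id, labels$haplotype_index, labels$chrom,
                     drop = TRUE)
  parts <- split(labels, key)
  out <- lapply(parts, function(d) {
    if (is.unsorted(d$pos, strictly = TRUE))
      stop("input error: site positions must be strictly increasing per ",
           "haplotype (", d$sample_id[1L], " hap ", d$haplotype_index[1L],
           " ", d$chrom[1L], ")", call. = FALSE)
    r <- rle(d$ancestry)
    last <- cumsum(r$lengths)
    first <- c(1L, utils::head(last, -1L) + 1L)
    data.frame(sample_id = d$sample_id[1L],
               haplotype_index = d$haplotype_index[1L],
               chrom = d$chrom[1L],
               start = d$pos[first] - 1, end = d$pos[last],
               ancestry = r$values, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Expand tracts back to per-site ancestry labels
#'
#' Inverse of [collapse_tracts()] at the assayed sites: looks up the tract
#' covering each queried (1-based) position. Positions covered by no tract
#' get "UNK".
#'
#' @param tracts Tract data.frame.
#' @param sites Data.frame (sample_id, haplotype_index, chrom, pos).
#' @return `sites` with an `ancestry` column appended.
#' @export
expand_tracts <- function(tracts, sites) {
  key_t <- interaction(tracts$sample_id, tracts$haplotype_index, tracts$chrom,
                       drop = TRUE)
  tparts <- split(tracts, key_t)
  key_s <- interaction(sites$sample_id, sites$haplotype_index, sites$chrom,
                       drop = TRUE)
  lab <- rep(NA_character_, nrow(sites))
  for (k in levels(key_s)) {
    idx <- which(key_s == k)
    tr <- tparts[[k]]
    if (is.null(tr)) { lab[idx] <- "UNK"; next }
    tr <- tr[order(tr$start), ]
    l <- tract_lookup(tr$start, tr$end, tr$ancestry, sites$pos[idx])
    l[is.na(l)] <- "UNK"
    lab[idx] <- l
  }
  sites$ancestry <- lab
  sites
}

#' Global-ancestry fractions from local-ancestry tracts
#'
#' Per sample, the fraction of each named population is its total tract
#' length over both haplotypes divided by the total length assigned to any
#' named population (UNK excluded from the denominator); the UNK share of the
#' total tract length is reported separately.
#'
#' @param tracts Tract data.frame.
#' @return Data.frame: sample_id, EUR, AFR, ASN, unknown_fraction.
#' @export
global_fractions <- function(tracts) {
  pops <- c("EUR", "AFR", "ASN")
  len <- tracts$end - tracts$start
  agg <- stats::aggregate(len, by = list(sample_id = tracts$sample_id,
                                         ancestry = tracts$ancestry), FUN = sum)
  ids <- unique(tracts$sample_id)
  out <- data.frame(sample_id = ids, EUR = 0, AFR = 0, ASN = 0, UNK = 0,
                    stringsAsFactors = FALSE)
  i <- match(agg$sample_id, out$sample_id)
  j <- match(agg$ancestry, c(pops, "UNK")) + 1L
  out[cbind(i, j)] <- agg$x
  assigned <- rowSums(out[, pops])
  total <- assigned + out$UNK
  zero <- which(assigned == 0)
  if (length(zero) > 0L)
    stop("sample with zero assigned (non-UNK) tract length: ",
         paste(out$sample_id[zero], collapse = ", "), call. = FALSE)
  res <- data.frame(sample_id = out$sample_id,
                    EUR = out$EUR / assigned, AFR = out$AFR / assigned,
                    ASN = out$ASN / assigned,
                    unknown_fraction = out$UNK / total,
                    stringsAsFactors = FALSE)
  res[order(res$sample_id), , drop = FALSE]
}

#' Select admixed samples by global-ancestry cutoff
#'
#' A sample is admixed if no single named population accounts for `cutoff`
#' (default 90\%) or more of its assigned global ancestry (strict
#' inequality: a sample at exactly the cutoff is excluded).
#'
#' @param ga Data.frame from [global_fractions()].
#' @param cutoff Maximum single-population fraction; default 0.9.
#' @return Character vector of retained sample ids.
#' @export
select_admixed <- function(ga, cutoff = 0.9) {
  mx <- pmax(ga$EUR, ga$AFR, ga$ASN)
  ga$sample_id[mx < cutoff]
}

#' Filter variants by minor allele count
#'
#' @param genotypes Variants x samples dosage matrix in \{0, 1, 2\}.
#' @param samples Sample ids defining the analysis cohort; default all.
#' @param min_mac Minimum minor allele count (inclusive); default 10.
#' @return Character vector of retained variant ids (rownames).
#' @export
mac_filter <- function(genotypes, samples = colnames(genotypes),
                       min_mac = 10L) {
  g <- genotypes[, samples, drop = FALSE]
  alt <- rowSums(g)
  mac <- pmin(alt, 2L * ncol(g) - alt)
  rownames(g)[mac >= min_mac]
}

#' Per-variant local-ancestry allele counts
#'
#' For each queried site and sample, counts how many of the two haplotypes'
#' covering tracts are EUR, AFR, ASN or UNK. Positions not covered by any
#' tract count as UNK, so counts always sum to 2.
#'
#' @param tracts Tract data.frame.
#' @param sites Data.frame with columns chrom, pos (1-based) and variant_id.
#' @param samples Sample ids to count for; default all samples in `tracts`.
#' @return A list of four sites x samples integer matrices: `eur`, `afr`,
#'   `asn`, `unk`, with `variant_id` rownames.
#' @export
la_counts <- function(tracts, sites, samples = NULL) {
  if (is.null(samples)) samples <- unique(tracts$sample_id)
  n_s <- nrow(sites)
  mk <- function() matrix(0L, nrow = n_s, ncol = length(samples),
                          dimnames = list(sites$variant_id, samples))
  counts <- list(eur = mk(), afr = mk(), asn = mk(), unk = mk())
  slot_of <- c(EUR = "eur", AFR = "afr", ASN = "asn", UNK = "unk")
  key_t <- interaction(tracts$sample_id, tracts$haplotype_index, tracts$chrom,
                       drop = TRUE)
  tparts <- split(tracts, key_t)
  by_chrom <- split(seq_len(n_s), sites$chrom)
  for (s in samples) {
    for (h in 0:1) {
      for (chrom in names(by_chrom)) {
        idx <- by_chrom[[chrom]]
        tr <- tparts[[paste(s, h, chrom, sep = ".")]]
        if (is.null(tr)) {
          counts$unk[idx, s] <- counts$unk[idx, s] + 1L
          next
        }
        tr <- tr[order(tr$start), ]
        if (nrow(tr) > 1L && any(tr$start[-1L] < tr$end[-nrow(tr)]))
          stop("input error: overlapping tracts for sample ", s,
               " haplotype ", h, " on ", chrom, call. = FALSE)
        lab <- tract_lookup(tr$start, tr$end, tr$ancestry, sites$pos[idx])
        lab[is.na(lab)] <- "UNK"
        for (a in names(slot_of)) {
          hit <- idx[lab == a]
          if (length(hit) > 0L)
            counts[[slot_of[[a]]]][hit, s] <- counts[[slot_of[[a]]]][hit, s] + 1L
        }
      }
    }
  }
  counts
}
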