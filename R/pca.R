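#' Genotype principal components
#'
#' Standardized-genotype SVD in the EIGENSTRAT style: variants are filtered by
#' call rate and MAF, LD-pruned with a greedy sliding window (50 variants,
#' step 5, removing the later variant of any pair with r-squared above
#' `ld_r2_max`), then each variant is centered at 2p and scaled by
#' sqrt(2p(1 - p)); missing entries are mean-imputed (zero after centering).
#' The per-component sign is fixed by making the variant loading of largest
#' magnitude positive.
#'
#' @param dosages Variants x samples matrix in \{0, 1, 2\} with possible NAs.
#' @param maf_min Minimum minor allele frequency; default 0.05.
#' @param call_rate_min Minimum per-variant call rate; default 0.99.
#' @param ld_r2_max r-squared above which the later variant of a window pair
#'   is pruned; default 0.2.
#' @param n_components Number of components to return; default 5.
#' @param ld_window,ld_step Sliding-window size and step for pruning.
#' @return Object of class `genotype_pcs`: list with `scores` (samples x
#'   components, columns PC1..), `explained_variance_fraction`,
#'   `variants_used`.
#' @export
genotype_pca <- function(dosages, maf_min = 0.05, call_rate_min = 0.99,
                         ld_r2_max = 0.2, n_components = 5L,
                         ld_window = 50L, ld_step = 5L) {
  call_rate <- rowMeans(!is.na(dosages))
  p <- rowMeans(dosages, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  ok <- call_rate >= call_rate_min & maf >= maf_min & p > 0 & p < 1
  # zero-variance columns can survive the frequency filter only when all
  # observed dosages are equal; drop them too
  vr <- apply(dosages, 1L, stats::var, na.rm = TRUE)
  ok <- ok & !is.na(vr) & vr > 0
  g <- dosages[ok, , drop = FALSE]
  p <- p[ok]

  if (nrow(g) > 1L) {
    gi <- g
    if (anyNA(gi)) {
      rm_ <- rowMeans(gi, na.rm = TRUE)
      na_idx <- which(is.na(gi), arr.ind = TRUE)
      gi[na_idx] <- rm_[na_idx[, 1L]]
    }
    keep <- rep(TRUE, nrow(gi))
    starts <- seq(1L, nrow(gi), by = ld_step)
    for (s in starts) {
      win <- s:min(s + ld_window - 1L, nrow(gi))
      win <- win[keep[win]]
      if (length(win) < 2L) next
      r2 <- stats::cor(t(gi[win, , drop = FALSE]))^2
      for (a in seq_along(win)) {
        if (!keep[win[a]]) next
        hits <- which(r2[a, ] > ld_r2_max)
        hits <- hits[hits > a]
        keep[win[hits]] <- FALSE
      }
    }
    g <- g[keep, , drop = FALSE]
    p <- p[keep]
  }
  if (nrow(g) < n_components)
    stop("fewer retained variants (", nrow(g), ") than requested components (",
         n_components, ")", call. = FALSE)

  x <- (g - 2 * p) / sqrt(2 * p * (1 - p))
  x[is.na(x)] <- 0
  # center samples-by-variants columns so scores have mean zero
  xt <- t(x)
  xt <- sweep(xt, 2L, colMeans(xt))
  sv <- svd(xt, nu = n_components, nv = n_components)
  flip <- vapply(seq_len(n_components), function(k) {
    v <- sv$v[, k]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components) %*%
    diag(flip, n_components)
  rownames(scores) <- colnames(dosages)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  structure(list(scores = scores,
                 explained_variance_fraction =
                   (sv$d^2 / sum(sv$d^2))[seq_len(n_components)],
                 variants_used = nrow(g)),
            class = "genotype_pcs")
}

#' Correlation between genotype PCs and global-ancestry fractions
#'
#' @param pcs A [genotype_pca()] result.
#' @param ga A [global_fractions()] table covering the same samples.
#' @return Matrix of Pearson correlations, components x populations.
#' @export
correlate_gpcs_ga <- function(pcs, ga) {
  ids <- intersect(rownames(pcs$scores), ga$sample_id)
  if (length(ids) < 3L)
    stop("need at least 3 shared samples to correlate", call. = FALSE)
  gam <- as.matrix(ga[match(ids, ga$sample_id), c("EUR", "AFR", "ASN")])
  stats::cor(pcs$scores[ids, , drop = FALSE], gam)
}
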