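#' Write phased haplotypes as a minimal VCF
#'
#' Emits a VCFv4.2 file with one biallelic record per variant and phased GT
#' fields (`a|b`).
#'
#' @param haplotypes Variants x 2n binary matrix (columns `<sample>.0`,
#'   `<sample>.1`).
#' @param variants Data.frame (chrom, pos, variant_id, ref, alt) aligned with
#'   the haplotype rows.
#' @param path Output file.
#' @export
write_phased_vcf <- function(haplotypes, variants, path) {
  odd <- seq(1L, ncol(haplotypes), by = 2L)
  samples <- sub("\\.0$", "", colnames(haplotypes)[odd])
  gt <- matrix(paste(haplotypes[, odd], haplotypes[, odd + 1L], sep = "|"),
               nrow = nrow(haplotypes))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste(variants$chrom, variants$pos, variants$variant_id,
                variants$ref, variants$alt, ".", ".", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
}

#' Read phased haplotypes from a VCF
#'
#' Parses a phased VCF (GT with `|` separators, one ALT per record) into the
#' haplotype-matrix representation the simulator produces. Requires the vcfR
#' package.
#'
#' @param path VCF file.
#' @return List with `haplotypes` and `variants` as in [write_phased_vcf()].
#' @export
read_phased_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCFs requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         variant_id = fix$ID, ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  a0 <- matrix(as.integer(substr(gt, 1L, 1L)), nrow = nrow(gt))
  a1 <- matrix(as.integer(substr(gt, 3L, 3L)), nrow = nrow(gt))
  haps <- matrix(0L, nrow = nrow(gt), ncol = 2L * ncol(gt))
  haps[, seq(1L, ncol(haps), 2L)] <- a0
  haps[, seq(2L, ncol(haps), 2L)] <- a1
  colnames(haps) <- as.vector(t(outer(colnames(gt), 0:1, paste, sep = ".")))
  rownames(haps) <- variants$variant_id
  list(haplotypes = haps, variants = variants)
}

#' Write local-ancestry tracts as BED
#'
#' Tab-delimited, 0-based half-open: chrom, start, end, ancestry, sample_id,
#' haplotype_index. No header line.
#'
#' @param tracts Tract data.frame.
#' @param path Output file.
#' @export
write_tracts_bed <- function(tracts, path) {
  utils::write.table(
    tracts[, c("chrom", "start", "end", "ancestry", "sample_id",
               "haplotype_index")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
}

#' Read a tracts BED written by [write_tracts_bed()]
#' @param path BED file.
#' @return Tract data.frame.
#' @export
read_tracts_bed <- function(path) {
  d <- utils::read.delim(path, header = FALSE,
                         col.names = c("chrom", "start", "end", "ancestry",
                                       "sample_id", "haplotype_index"),
                         stringsAsFactors = FALSE)
  d[, c("sample_id", "haplotype_index", "chrom", "start", "end", "ancestry")]
}

write_tsv <- function(d, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    d <- cbind(stats::setNames(data.frame(rownames(d),
                                          stringsAsFactors = FALSE),
                               rownames_as),
               as.data.frame(d))
  }
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
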