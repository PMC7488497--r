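#!/usr/bin/env Rscript
# Stage 7: screen lead eVariants for genotype/local-ancestry confounding.
# Each unique eVariant is regressed (minor-allele dosage on AFR + ASN allele
# counts) in two scopes: the full genotyped cohort, and per tissue on the
# samples with expression. Associations with R^2 > 0.7 are exported.

library(admixqtl)

out <- "results"
st1 <- readRDS(file.path(out, "state", "01_cohort.rds"))
st2 <- readRDS(file.path(out, "state", "02_tracts.rds"))
st5 <- readRDS(file.path(out, "state", "05_eqtl.rds"))
cohort <- st1$cohort

lead_vars <- sort(unique(unlist(c(
  st5$leads_local$lead_variants[st5$leads_local$is_egene],
  st5$leads_global$lead_variants[st5$leads_global$is_egene]))))
if (length(lead_vars) == 0L) {
  cat("No significant eVariants to screen.\n")
} else {
  sites <- cohort$panel$variants[
    cohort$panel$variants$variant_id %in% lead_vars,
    c("chrom", "pos", "variant_id")]
  la_all <- la_counts(cohort$tracts, sites, samples = cohort$sample_ids)
  tissues <- unique(st5$leads_local$tissue)
  tissue_samples <- setNames(rep(list(st2$admixed), length(tissues)), tissues)
  scr <- screen_confounding(list(st5$leads_local, st5$leads_global),
                            cohort$dosages[lead_vars, , drop = FALSE],
                            la_all, tissue_samples)
  write.table(scr$all_samples, file.path(out, "confounding_all_samples.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(scr$by_tissue, file.path(out, "confounding_by_tissue.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(scr$flagged, file.path(out, "confounding_flagged.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("Screened %d eVariants (%d tissue records); %d associations with R^2 > 0.7, %d with R^2 > 0.9.\n",
              nrow(scr$all_samples), nrow(scr$by_tissue), nrow(scr$flagged),
              sum(scr$flagged$flag_09)))
}
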