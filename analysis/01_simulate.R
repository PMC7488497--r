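#!/usr/bin/env Rscript
# Stage 1: generate the synthetic admixed cohort the rest of the workflow
# analyses — 117 individuals, three ancestral populations (EUR/AFR/ASN,
# F_ST = 0.15), Dirichlet(3, 2, 1) admixture, seven "tissues" sharing one
# set of genotypes, and a GWAS cohort for colocalization.

library(admixqtl)

out <- "results"
dir.create(file.path(out, "state"), recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_individuals = 117L, n_chromosomes = 2L,
                  n_variants_per_chrom = 1000L, n_genes = 60L,
                  n_tissues = 7L, gwas_n = 1000L, seed = 2024L)
cohort <- simulate_cohort(cfg)
gwas <- simulate_gwas(cohort, cfg)

write_phased_vcf(cohort$haplotypes, cohort$panel$variants,
                 file.path(out, "genotypes.vcf"))
write_tracts_bed(cohort$tracts, file.path(out, "true_tracts.bed"))
write.table(cohort$gene_annot, file.path(out, "gene_annotation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
for (t in names(cohort$expression)) {
  write.table(data.frame(gene_id = rownames(cohort$expression[[t]]),
                         cohort$expression[[t]], check.names = FALSE),
              file.path(out, paste0("expression_", t, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
saveRDS(list(config = cfg, cohort = cohort, gwas = gwas),
        file.path(out, "state", "01_cohort.rds"))

cat(sprintf("Simulated %d individuals, %d variants, %d genes x %d tissues; %d GWAS traits.\n",
            cfg$n_individuals, nrow(cohort$panel$variants), cfg$n_genes,
            cfg$n_tissues, nrow(gwas$traits)))
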