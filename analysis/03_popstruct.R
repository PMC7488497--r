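#!/usr/bin/env Rscript
# Stage 3: genotype PCA on the admixed cohort (MAF >= 0.05, call rate >= 0.99,
# greedy LD pruning at r^2 > 0.2) and its correlation with tract-derived
# global-ancestry fractions. Leading gPCs should align with the AFR and ASN
# admixture axes.

library(admixqtl)

out <- "results"
st1 <- readRDS(file.path(out, "state", "01_cohort.rds"))
st2 <- readRDS(file.path(out, "state", "02_tracts.rds"))

pcs <- genotype_pca(st1$cohort$dosages[st2$kept, st2$admixed, drop = FALSE],
                    n_components = 5L)
r <- correlate_gpcs_ga(pcs, st2$ga)

write.table(data.frame(sample_id = rownames(pcs$scores), pcs$scores),
            file.path(out, "gpc_scores.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(component = rownames(r), round(r, 4)),
            file.path(out, "gpc_ga_correlation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
saveRDS(pcs, file.path(out, "state", "03_pcs.rds"))

cat(sprintf("PCA on %d variants; max |r| with AFR fraction: %.3f, with ASN: %.3f.\n",
            pcs$variants_used, max(abs(r[, "AFR"])), max(abs(r[, "ASN"]))))
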