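#!/usr/bin/env Rscript
# Stage 2: per-site ancestry posteriors -> hard assignments (posterior >= 0.9)
# -> collapsed haplotype tracts -> global-ancestry fractions -> admixed-sample
# selection (< 90% single-population ancestry) -> MAC >= 10 variant filter ->
# per-variant local-ancestry allele counts.

library(admixqtl)

out <- "results"
st <- readRDS(file.path(out, "state", "01_cohort.rds"))
cohort <- st$cohort

posteriors <- emit_site_posteriors(cohort)
labels <- assign_sites(posteriors, threshold = 0.9)
tracts <- collapse_tracts(labels)
ga <- global_fractions(tracts)
admixed <- select_admixed(ga, cutoff = 0.9)
kept <- mac_filter(cohort$dosages, admixed, min_mac = 10L)
sites <- cohort$panel$variants[cohort$panel$variants$variant_id %in% kept,
                               c("chrom", "pos", "variant_id")]
la <- la_counts(cohort$tracts, sites, samples = admixed)

write_tracts_bed(tracts, file.path(out, "tracts.bed"))
write.table(ga, file.path(out, "global_ancestry.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(admixed, file.path(out, "admixed_samples.txt"))
saveRDS(list(tracts = tracts, ga = ga, admixed = admixed, kept = kept,
             sites = sites, la = la),
        file.path(out, "state", "02_tracts.rds"))

cat(sprintf("Collapsed %d tracts; %d/%d samples admixed; %d/%d variants pass MAC >= 10.\n",
            nrow(tracts), length(admixed), nrow(ga), length(kept),
            nrow(cohort$panel$variants)))
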