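#' Run the full synthetic-cohort analysis pipeline
#'
#' Orchestrates simulate -> ancestry tracts -> genotype PCA -> variance
#' partition -> dual-adjustment eQTL mapping -> GWAS colocalization ->
#' confounding screen under one configuration, writing every stage's tables
#' under `out_dir` and returning a manifest plus the summary objects the
#' report renders.
#'
#' @param config A [sim_config()]; its seed drives every stage.
#' @param out_dir Output directory (created if needed).
#' @param n_hidden Number of expression-PC hidden confounders in the eQTL
#'   covariates.
#' @param min_n Minimum post-exclusion sample size for the LocalAA fit.
#' @return Object of class `admix_run`: list with `manifest` (config hash,
#'   seed, version, stage table) and `summary` (eGene counts, binomial tail
#'   probability, lead comparison, colocalization concordance, confounding
#'   flags).
#' @export
run_admix_pipeline <- function(config, out_dir, n_hidden = 3L, min_n = 30L) {
  validate_sim_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  emit <- function(stage, file, obj, writer = write_tsv, ...) {
    path <- file.path(out_dir, file)
    writer(obj, path, ...)
    n <- if (is.data.frame(obj) || is.matrix(obj)) nrow(obj) else length(obj)
    stages[[length(stages) + 1L]] <<- data.frame(
      stage = stage, output = file, rows = n, stringsAsFactors = FALSE)
    invisible(path)
  }
  run_stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e)
      stop("stage `", name, "` failed: ", conditionMessage(e), call. = FALSE))
  }

  cfg_path <- file.path(out_dir, "config.txt")
  writeLines(paste(names(unclass(config)),
                   vapply(unclass(config), function(x)
                     paste(format(x), collapse = ","), character(1)),
                   sep = "\t"), cfg_path)

  ## 1. simulate -------------------------------------------------------------
  cohort <- run_stage("simulate", simulate_cohort(config))
  emit("simulate", "genotypes.vcf",
       NULL, writer = function(obj, path)
         write_phased_vcf(cohort$haplotypes, cohort$panel$variants, path))
  stages[[length(stages)]]$rows <- nrow(cohort$panel$variants)
  emit("simulate", "gene_annotation.tsv", cohort$gene_annot)
  for (t in names(cohort$expression)) {
    emit("simulate", paste0("expression_", t, ".tsv"),
         cohort$expression[[t]], rownames_as = "gene_id")
    emit("simulate", paste0("truth_", t, ".tsv"), cohort$truth_by_tissue[[t]])
  }

  ## 2. ancestry tracts ------------------------------------------------------
  tract_out <- run_stage("tracts", {
    post <- emit_site_posteriors(cohort)
    labels <- assign_sites(post)
    tracts <- collapse_tracts(labels)
    ga <- global_fractions(tracts)
    admixed <- select_admixed(ga)
    kept <- mac_filter(cohort$dosages, admixed)
    sites <- cohort$panel$variants[
      cohort$panel$variants$variant_id %in% kept,
      c("chrom", "pos", "variant_id")]
    la <- la_counts(cohort$tracts, sites, samples = admixed)
    list(tracts = tracts, ga = ga, admixed = admixed, kept = kept,
         sites = sites, la = la)
  })
  emit("tracts", "tracts.bed", tract_out$tracts, writer = write_tracts_bed)
  emit("tracts", "global_ancestry.tsv", tract_out$ga)
  emit("tracts", "admixed_samples.txt", tract_out$admixed,
       writer = function(obj, path) writeLines(obj, path))
  admixed <- tract_out$admixed
  la <- tract_out$la

  ## 3. genotype PCA ---------------------------------------------------------
  pcs <- run_stage("pca", genotype_pca(
    cohort$dosages[tract_out$kept, admixed, drop = FALSE]))
  emit("pca", "gpc_scores.tsv", pcs$scores, rownames_as = "sample_id")
  gpc_ga_cor <- correlate_gpcs_ga(pcs, tract_out$ga)

  ## 4. variance partition ---------------------------------------------------
  vp <- run_stage("variance_partition", {
    tss_sites <- data.frame(chrom = cohort$gene_annot$chrom,
                            pos = cohort$gene_annot$tss,
                            variant_id = cohort$gene_annot$gene_id,
                            stringsAsFactors = FALSE)
    la_tss <- la_counts(cohort$tracts, tss_sites, samples = admixed)
    res <- lapply(names(cohort$expression), function(t)
      run_variance_partition(cohort$expression[[t]][, admixed, drop = FALSE],
                             la_tss, pcs$scores, tissue = t))
    names(res) <- names(cohort$expression)
    res
  })
  emit("variance_partition", "variance_partition.tsv",
       do.call(rbind, lapply(vp, `[[`, "records")))

  ## 5. dual-adjustment eQTL mapping -----------------------------------------
  eqtl_out <- run_stage("eqtl", {
    cis <- cis_pairs(cohort$gene_annot,
                     tract_out$sites[, c("variant_id", "chrom", "pos")])
    leads_l <- leads_g <- list()
    all_recs <- list()
    for (t in names(cohort$expression)) {
      expr <- cohort$expression[[t]][, admixed, drop = FALSE]
      covars <- build_covariates(NULL, expr, n_hidden = n_hidden)
      rl <- map_eqtls(expr, cohort$dosages, cis, covars, la = la,
                      method = "local", min_n = min_n)
      rg <- map_eqtls(expr, cohort$dosages, cis, covars, gpcs = pcs$scores,
                      method = "global")
      ll <- call_leads(rl); ll$tissue <- t
      lg <- call_leads(rg); lg$tissue <- t
      leads_l[[t]] <- ll
      leads_g[[t]] <- lg
      rl$tissue <- rg$tissue <- t
      all_recs[[t]] <- rbind(rl, rg)
    }
    list(records = do.call(rbind, all_recs),
         leads_local = do.call(rbind, leads_l),
         leads_global = do.call(rbind, leads_g))
  })
  emit("eqtl", "eqtl_records.tsv", eqtl_out$records)
  flatten_leads <- function(ld) {
    ld$lead_variants <- vapply(ld$lead_variants, paste, character(1),
                               collapse = ";")
    ld
  }
  emit("eqtl", "leads_local.tsv", flatten_leads(eqtl_out$leads_local))
  emit("eqtl", "leads_global.tsv", flatten_leads(eqtl_out$leads_global))
  cmp <- compare_methods(eqtl_out$leads_local, eqtl_out$leads_global,
                         cohort$dosages[, admixed, drop = FALSE])
  emit("eqtl", "lead_comparison.tsv", cmp$comparison)
  emit("eqtl", "egene_counts.tsv", cmp$egene_counts)

  ## 6. GWAS colocalization --------------------------------------------------
  coloc_out <- run_stage("coloc", {
    gwas <- simulate_gwas(cohort, config)
    vv <- cohort$panel$variants
    scores <- list()
    for (j in seq_len(nrow(gwas$traits))) {
      tid <- gwas$traits$trait_id[j]
      gstats <- gwas$stats[[tid]]
      seeds <- scan_seeds(gstats)
      g <- gwas$traits$gene_id[j]
      for (si in seq_len(nrow(seeds))) {
        for (t in names(cohort$expression)) {
          for (adj in c("LocalAA", "GlobalAA")) {
            er <- eqtl_out$records[eqtl_out$records$gene_id == g &
                                     eqtl_out$records$method == adj &
                                     eqtl_out$records$tissue == t &
                                     !eqtl_out$records$skipped, ,
                                   drop = FALSE]
            if (nrow(er) == 0L) next
            er <- cbind(er, vv[match(er$variant_id, vv$variant_id),
                               c("chrom", "pos", "ref", "alt")])
            er$n <- er$n_effective
            er$z <- er$t_stat
            er$case_fraction <- NA_real_
            er$trait_type <- "quant"
            locus <- build_locus(seeds[si, ], gstats, er)
            if (is.null(locus)) next
            sc <- score_locus(locus, run_finemap = FALSE)
            scores[[paste(tid, t, adj, si)]] <- data.frame(
              locus_id = paste(tid, g, t, seeds$variant_id[si], sep = ":"),
              trait_id = tid, gene_id = g, tissue = t, adjustment = adj,
              n_variants = length(locus$variants),
              t(sc$pp), clpp = NA_real_, stringsAsFactors = FALSE)
            attr(scores[[paste(tid, t, adj, si)]], "locus") <- locus
          }
        }
      }
    }
    if (length(scores) == 0L) {
      list(scores = NULL, concordance = NULL)
    } else {
      df <- do.call(rbind, scores)
      rownames(df) <- NULL
      # FINEMAP stage only where COLOC called a colocalization at the locus
      called <- unique(df$locus_id[df$PP4 > 0.5])
      for (k in seq_along(scores)) {
        if (!(scores[[k]]$locus_id %in% called)) next
        locus <- attr(scores[[k]], "locus")
        sc <- score_locus(locus, run_finemap = TRUE)
        df$clpp[k] <- sc$clpp
      }
      conc <- classify_concordance(
        data.frame(locus_id = df$locus_id, adjustment = df$adjustment,
                   pp4 = df$PP4, clpp = df$clpp, stringsAsFactors = FALSE))
      list(scores = df, concordance = conc)
    }
  })
  if (!is.null(coloc_out$scores)) {
    emit("coloc", "coloc_scores.tsv", coloc_out$scores)
    emit("coloc", "coloc_concordance.tsv", coloc_out$concordance)
  }

  ## 7. confounding screen ---------------------------------------------------
  conf <- run_stage("confounding", {
    lead_vars <- sort(unique(unlist(c(
      eqtl_out$leads_local$lead_variants[eqtl_out$leads_local$is_egene],
      eqtl_out$leads_global$lead_variants[eqtl_out$leads_global$is_egene]))))
    if (length(lead_vars) == 0L) {
      list(all_samples = NULL, by_tissue = NULL, flagged = NULL)
    } else {
      sites <- cohort$panel$variants[
        cohort$panel$variants$variant_id %in% lead_vars,
        c("chrom", "pos", "variant_id")]
      la_all <- la_counts(cohort$tracts, sites, samples = cohort$sample_ids)
      tissue_samples <- stats::setNames(
        rep(list(admixed), config$n_tissues), names(cohort$expression))
      screen_confounding(list(eqtl_out$leads_local, eqtl_out$leads_global),
                         cohort$dosages[lead_vars, , drop = FALSE],
                         la_all, tissue_samples)
    }
  })
  if (!is.null(conf$all_samples)) {
    emit("confounding", "confounding_all_samples.tsv", conf$all_samples)
    emit("confounding", "confounding_by_tissue.tsv", conf$by_tissue)
    emit("confounding", "confounding_flagged.tsv", conf$flagged)
  }

  stage_df <- do.call(rbind, stages)
  missing <- !file.exists(file.path(out_dir, stage_df$output))
  if (any(missing))
    stop("declared outputs missing: ",
         paste(stage_df$output[missing], collapse = ", "), call. = FALSE)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    version = as.character(utils::packageVersion("admixqtl")),
    stages = stage_df)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res <- list(manifest = manifest,
              summary = list(egene_counts = cmp$egene_counts,
                             binomial_p = cmp$binomial_p,
                             lead_comparison = cmp$comparison,
                             gpc_ga_cor = gpc_ga_cor,
                             variance_partition = vp,
                             concordance = coloc_out$concordance,
                             confounding_flagged = conf$flagged))
  class(res) <- "admix_run"
  writeLines(report(res), file.path(out_dir, "report.md"))
  res
}

#' Render a pipeline run as a markdown report
#'
#' Deterministic (no timestamps): per-tissue eGene counts with the binomial
#' tail probability, same/different-lead counts, colocalization concordance
#' classes, and confounding flags.
#'
#' @param run An `admix_run` from [run_admix_pipeline()].
#' @return Character vector of markdown lines.
#' @export
report <- function(run) {
  if (!inherits(run, "admix_run") || is.null(run$summary))
    stop("incomplete run: no summary to report", call. = FALSE)
  s <- run$summary
  lines <- c("# Admixed-cohort eQTL pipeline report", "",
             sprintf("Seed: %d; config hash: %s", run$manifest$seed,
                     run$manifest$config_hash), "",
             "## eGenes per tissue (p < 1e-6)", "",
             "| tissue | LocalAA | GlobalAA |", "|---|---|---|")
  ec <- s$egene_counts
  lines <- c(lines, sprintf("| %s | %d | %d |", ec$tissue, ec$n_local,
                            ec$n_global))
  k <- sum(ec$n_local > ec$n_global)
  lines <- c(lines, "",
             sprintf(paste0("LocalAA found more eGenes in %d of %d tissues; ",
                            "one-sided binomial tail probability %.4g."),
                     k, nrow(ec), s$binomial_p), "",
             "## Lead eVariants", "",
             sprintf("Same lead: %d genes; different leads: %d genes.",
                     sum(s$lead_comparison$same_lead),
                     sum(s$lead_comparison$different_leads)))
  if (!is.null(s$concordance)) {
    lines <- c(lines, "", "## Colocalization concordance", "",
               sprintf("Loci scored: %d; flagged discordant-adjustment: %d.",
                       nrow(s$concordance), sum(s$concordance$flagged)))
  }
  if (!is.null(s$confounding_flagged)) {
    lines <- c(lines, "", "## Local-ancestry confounding", "",
               sprintf("Associations with R^2 > 0.7: %d.",
                       nrow(s$confounding_flagged)))
  }
  lines
}
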