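## End-to-end orchestration: simulate (optional) -> traits -> trait stats ->
## wax -> selection scan -> differential expression, from a single config,
## with a manifest and per-stage logging.

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' A fully simulated demo configuration with the analysis defaults: 90 min
#' plateau onset, 0.3% SNP outlier fraction, 5 kb flanks, top-50% candidate
#' genes, FDR < 0.1, total-count filter > 1000. Planted effects: lower alpine
#' minimum conductance, 2-fold alpine increase of two wax compounds, 10 genes
#' with allele-frequency shift 0.5, and 20 genes with log2 fold-change 2.
#'
#' @param seed Integer master seed.
#' @return Nested list understood by [run_pipeline()].
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    stages = list(traits = TRUE, stats = TRUE, wax = TRUE, scan = TRUE,
                  dge = TRUE),
    parameters = list(plateau_start_min = 90, top_snp_frac = 0.003,
                      flank = 5000, top_gene_frac = 0.5, fdr = 0.1,
                      min_total = 1000, wax_alpha = 0.05),
    simulate = list(
      n_regions = 3, pops_per_ecotype_per_region = 2,
      leaves_per_population = 14,
      trait_effects = list(gmin = list(ecotype = -0.5),
                           wsd = list(ecotype = -0.3)),
      sigma_pop = 0.1, sigma_resid = 0.3,
      wax_fold_changes = c(`1-hexacosanol` = 2, `iso-nonacosane` = 2),
      wax_lognormal_sd = 0.3, wax_samples_per_population = 9,
      n_genes = 100, n_snps_per_gene = 100, n_selected_genes = 10,
      afd_shift = 0.5, n_individuals_per_pop = 7,
      n_count_genes = 1000, n_de_genes = 20, lfc = 2, dispersion = 0.1))
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys as in [default_config()]. Missing keys fall
#'   back to the defaults.
#' @return Config list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config(seed = if (is.null(user$seed)) 1 else user$seed)
  for (k in names(user)) {
    if (is.list(cfg[[k]]) && is.list(user[[k]])) {
      for (kk in names(user[[k]])) cfg[[k]][[kk]] <- user[[k]][[kk]]
    } else cfg[[k]] <- user[[k]]
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order (simulate inputs, reduce drying
#' curves and droplet geometry to traits, trait mixed-model ANOVA tables, wax
#' normalization and per-compound tests, AFD selection scan, differential
#' expression) and writes every stage's table plus a JSON manifest to
#' `out_dir`. The run is deterministic given the config (stage seeds are
#' derived from the master seed). On stage failure a `FAILED` marker naming
#' the stage is written and the error re-thrown; earlier outputs are kept.
#'
#' @param config Config list as from [default_config()] or [read_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results of each stage.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$parameters
  sim <- config$simulate
  seed <- config$seed
  results <- list()
  stage <- "design"
  on.exit({
    writeLines(paste("failed at stage:", stage), file.path(out_dir, "FAILED"))
  })
  log_stage <- function(name, msg) message(sprintf("[%s] %s", name, msg))

  design <- make_design(sim$n_regions, sim$pops_per_ecotype_per_region,
                        sim$leaves_per_population, seed = seed)
  results$design <- design

  if (isTRUE(config$stages$traits)) {
    stage <- "traits"
    traits <- simulate_traits(design, fixed_effects = sim$trait_effects,
                              sigma_pop = sim$sigma_pop,
                              sigma_resid = sim$sigma_resid, seed = seed + 1)
    write_tsv(traits, file.path(out_dir, "traits.tsv"))
    log_stage(stage, sprintf("%d leaves", nrow(traits)))
    results$traits <- traits
  }

  if (isTRUE(config$stages$stats)) {
    stage <- "stats"
    tabs <- trait_anova_tables(results$traits)
    an <- do.call(rbind, lapply(names(tabs), function(tr)
      cbind(trait = tr, tabs[[tr]]$anova)))
    write_tsv(an, file.path(out_dir, "trait_anova.tsv"))
    log_stage(stage, sprintf("%d ANOVA rows over %d traits", nrow(an),
                             length(tabs)))
    results$stats <- tabs
  }

  if (isTRUE(config$stages$wax)) {
    stage <- "wax"
    peaks <- simulate_peak_table(
      design, fold_changes = sim$wax_fold_changes,
      lognormal_sd = sim$wax_lognormal_sd,
      samples_per_population = sim$wax_samples_per_population,
      seed = seed + 2)
    norm <- normalize_peaks(peaks)
    tests <- compound_tests(norm, alpha = p$wax_alpha)
    write_tsv(norm, file.path(out_dir, "wax_normalized.tsv"))
    write_tsv(tests, file.path(out_dir, "wax_tests.tsv"))
    log_stage(stage, sprintf("%d compounds tested, %d flagged", nrow(tests),
                             sum(tests$flagged)))
    results$wax <- list(normalized = norm, tests = tests)
  }

  if (isTRUE(config$stages$scan)) {
    stage <- "scan"
    gm <- simulate_gene_models(sim$n_genes, seed = seed + 3)
    selected <- utils::head(gm$genes$gene_id, sim$n_selected_genes)
    variants <- simulate_variants(design, sim$n_individuals_per_pop, gm,
                                  sim$n_snps_per_gene, selected,
                                  sim$afd_shift, flank = p$flank,
                                  seed = seed + 4)
    write_vcf(variants, file.path(out_dir, "variants.vcf"))
    write_gff3(gm, file.path(out_dir, "genes.gff3"))
    scan <- run_selection_scan(variants, gm, top_snp_frac = p$top_snp_frac,
                               flank = p$flank,
                               top_gene_frac = p$top_gene_frac)
    write_tsv(scan$snps, file.path(out_dir, "scan_snps.tsv"))
    write_tsv(scan$genes, file.path(out_dir, "scan_genes.tsv"))
    write_outlier_bed(scan, file.path(out_dir, "scan_outliers.bed"))
    log_stage(stage, sprintf("%d SNPs, %d outliers, %d candidates",
                             nrow(scan$snps), sum(scan$snps$outlier),
                             sum(scan$genes$candidate)))
    results$scan <- scan
    results$scan_truth <- selected
  }

  if (isTRUE(config$stages$dge)) {
    stage <- "dge"
    genes <- sprintf("g%04d", seq_len(sim$n_count_genes))
    de_genes <- utils::head(genes, sim$n_de_genes)
    sc <- simulate_counts(design, sim$n_count_genes, de_genes, sim$lfc,
                          sim$dispersion, seed = seed + 5)
    dge <- ecotype_test(sc$counts, sc$samples, fdr = p$fdr,
                        min_total = p$min_total)
    write_tsv(dge, file.path(out_dir, "dge.tsv"))
    log_stage(stage, sprintf("%d genes tested, %d DE at FDR < %g",
                             nrow(dge), sum(dge$de), p$fdr))
    results$dge <- dge
    results$dge_truth <- de_genes
  }

  stage <- "manifest"
  manifest <- list(
    seed = seed, parameters = p, simulate = sim,
    stages = config$stages,
    package_version = as.character(utils::packageVersion("cuticula")),
    r_version = R.version.string,
    outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  on.exit()  # completed: no FAILED marker
  invisible(results)
}
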