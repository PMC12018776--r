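## Synthetic-data generators: every pipeline input (trait tables, drying
## curves, tetraploid variants, GC-MS peak tables, RNA-seq counts) with the
## statistical structure the downstream analysis assumes.

#' Lay out a two-ecotype, multi-region common-garden study design
#'
#' Creates the population table of a reciprocal-transplant design: two
#' ecotypes (foothill, alpine) sampled from `n_regions` mountain ranges, with
#' `pops_per_ecotype_per_region` populations per ecotype and region, each
#' measured with `leaves_per_population` leaves in each of two common gardens.
#' Each population receives a standard-normal random-intercept draw per trait;
#' [simulate_traits()] scales these by its `sigma_pop`.
#'
#' @param n_regions Number of mountain ranges (>= 1; the study used 3).
#' @param pops_per_ecotype_per_region Populations per ecotype within each
#'   region (>= 1; the study used 2, i.e. six alpine plus six foothill
#'   populations).
#' @param leaves_per_population Leaves measured per population per garden
#'   (>= 1). The field protocol used 14.
#' @param seed Integer seed; the random intercept draws are deterministic
#'   given it.
#' @return An object of class `study_design`: list with `populations` (data
#'   frame: `population`, `ecotype`, `region`, one `z_<trait>` column per
#'   trait), `gardens`, `leaves_per_population`, `seed`.
#' @export
make_design <- function(n_regions = 3, pops_per_ecotype_per_region = 2,
                        leaves_per_population = 14, seed = 1) {
  if (n_regions < 1 || pops_per_ecotype_per_region < 1 ||
      leaves_per_population < 1)
    stop("all design counts must be >= 1")
  set.seed(seed)
  regions <- paste0("R", seq_len(n_regions))
  ecotypes <- c("foothill", "alpine")
  pops <- expand.grid(pop_idx = seq_len(pops_per_ecotype_per_region),
                      ecotype = ecotypes, region = regions,
                      stringsAsFactors = FALSE)
  pops$population <- sprintf("%s_%s_p%d", pops$region,
                             substr(pops$ecotype, 1, 3), pops$pop_idx)
  stopifnot(!anyDuplicated(pops$population))
  traits <- c("gmin", "wsd", "theta_adaxial", "theta_abaxial")
  for (tr in traits) pops[[paste0("z_", tr)]] <- stats::rnorm(nrow(pops))
  structure(
    list(populations = pops[, c("population", "ecotype", "region",
                                paste0("z_", traits))],
         gardens = c("foothill", "alpine"),
         leaves_per_population = leaves_per_population,
         traits = traits, seed = seed),
    class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(
    "<study_design> %d populations (%d regions x 2 ecotypes), %d leaves/population/garden\n",
    nrow(x$populations), length(unique(x$populations$region)),
    x$leaves_per_population))
  invisible(x)
}

default_trait_intercepts <- function() {
  ## transformed scale: ln g_min (m/s), sqrt WSD (%), sqrt theta (deg)
  c(gmin = log(1e-4), wsd = sqrt(15), theta_adaxial = sqrt(120),
    theta_abaxial = sqrt(110))
}

#' Simulate a leaf-level trait table under the analysis model
#'
#' Generates one row per leaf (population x garden x replicate) under exactly
#' the random-intercept linear model the statistics module fits, on the
#' transformed scale (ln for minimum conductance, square root for water
#' saturation deficit and contact angles), then inverts the transform to the
#' natural scale.
#'
#' `fixed_effects` is a per-trait list; each trait takes
#' `intercept`, `ecotype` (added for alpine plants), `garden` (added in the
#' alpine garden), `region` (vector, one entry per region),
#' `ecotype_garden`, and `ecotype_region` (vector) — all on the transformed
#' scale, all defaulting to 0 (intercepts default to field-realistic values).
#'
#' @param design A [make_design()] object.
#' @param fixed_effects Named list of per-trait effect lists (see Details).
#' @param sigma_pop Population random-intercept SD on the transformed scale
#'   (scalar or named per-trait vector).
#' @param sigma_resid Residual SD on the transformed scale (scalar or named
#'   per-trait vector).
#' @param seed Integer seed for the residual draws.
#' @return Data frame with columns `leaf_id`, `population`, `ecotype`,
#'   `region`, `garden`, `gmin_m_s`, `wsd_pct`, `theta_adaxial`,
#'   `theta_abaxial`.
#' @export
simulate_traits <- function(design, fixed_effects = list(),
                            sigma_pop = 0.1, sigma_resid = 0.3, seed = 1) {
  stopifnot(inherits(design, "study_design"))
  if (any(c(sigma_pop, sigma_resid) < 0)) stop("variance components must be >= 0")
  set.seed(seed)
  pops <- design$populations
  regions <- unique(pops$region)
  grid <- expand.grid(leaf = seq_len(design$leaves_per_population),
                      garden = design$gardens,
                      population = pops$population,
                      stringsAsFactors = FALSE)
  grid <- merge(grid, pops, by = "population")
  grid$leaf_id <- sprintf("%s_%s_l%02d", grid$population, grid$garden,
                          grid$leaf)
  grid <- grid[order(grid$leaf_id), ]
  n <- nrow(grid)
  intercepts <- default_trait_intercepts()
  sp <- rep_len(sigma_pop, length(design$traits))
  names(sp) <- design$traits
  if (!is.null(names(sigma_pop))) sp[names(sigma_pop)] <- sigma_pop
  sr <- rep_len(sigma_resid, length(design$traits))
  names(sr) <- design$traits
  if (!is.null(names(sigma_resid))) sr[names(sigma_resid)] <- sigma_resid
  out <- grid[, c("leaf_id", "population", "ecotype", "region", "garden")]
  alp <- as.numeric(grid$ecotype == "alpine")
  gard <- as.numeric(grid$garden == "alpine")
  ri <- match(grid$region, regions)
  for (tr in design$traits) {
    fe <- fixed_effects[[tr]]
    if (is.null(fe)) fe <- list()
    get1 <- function(nm, default = 0) if (is.null(fe[[nm]])) default else fe[[nm]]
    reg_eff <- rep_len(get1("region", rep(0, length(regions))), length(regions))
    ecoreg_eff <- rep_len(get1("ecotype_region", rep(0, length(regions))),
                          length(regions))
    y <- get1("intercept", intercepts[[tr]]) +
      get1("ecotype") * alp + get1("garden") * gard +
      reg_eff[ri] + get1("ecotype_garden") * alp * gard +
      ecoreg_eff[ri] * alp +
      sp[[tr]] * grid[[paste0("z_", tr)]] +
      stats::rnorm(n, 0, sr[[tr]])
    out[[tr]] <- y
  }
  ## invert transforms to natural scale
  out$gmin <- exp(out$gmin)
  out$wsd <- pmin(pmax(out$wsd, 0)^2, 100)
  out$theta_adaxial <- pmin(pmax(out$theta_adaxial, 0)^2, 179.9)
  out$theta_abaxial <- pmin(pmax(out$theta_abaxial, 0)^2, 179.9)
  names(out)[names(out) == "gmin"] <- "gmin_m_s"
  names(out)[names(out) == "wsd"] <- "wsd_pct"
  rownames(out) <- NULL
  out
}

#' Simulate a biphasic leaf drying curve
#'
#' Two-segment flux model of a detached drying leaf: mass falls at
#' `stomatal_rate` (g/min) until stomata close at `closure_time_min`, then at
#' `cuticular_rate` (the plateau the 90-min rule assumes), with optional
#' additive Gaussian measurement noise on mass. Masses are clipped so they
#' never fall below the dry mass nor exceed the saturation mass, and noise is
#' monotonised (running minimum) so the curve is non-increasing.
#'
#' @param leaf_area_m2 Leaf area (m^2).
#' @param sm_g,dm_g Saturation and dry mass (g), SM > DM > 0.
#' @param stomatal_rate,cuticular_rate Mass-loss rates (g min^-1) before and
#'   after stomatal closure; `stomatal_rate > cuticular_rate >= 0`.
#' @param closure_time_min Stomatal closure time (min, default 90).
#' @param interval_min Weighing interval (min, default 30).
#' @param n_points Number of weighings including t = 0 (default 6, i.e.
#'   0-150 min).
#' @param env Single-row data frame (`temp_c`, `rh_pct`, `pressure_kpa`)
#'   recycled to all timepoints, or one row per timepoint.
#' @param noise_sd Gaussian SD of mass measurement error (g, default 0).
#' @param leaf_id Label.
#' @param seed Integer seed.
#' @return A [drying_curve()].
#' @export
simulate_drying_curve <- function(leaf_area_m2, sm_g, dm_g, stomatal_rate,
                                  cuticular_rate, closure_time_min = 90,
                                  interval_min = 30, n_points = 6,
                                  env = data.frame(temp_c = 20, rh_pct = 50,
                                                   pressure_kpa = 101.3),
                                  noise_sd = 0, leaf_id = "leaf1", seed = 1) {
  if (!(sm_g > dm_g) || dm_g <= 0) stop("need SM > DM > 0")
  if (cuticular_rate < 0 || stomatal_rate <= cuticular_rate)
    stop("need stomatal_rate > cuticular_rate >= 0")
  set.seed(seed)
  times <- (seq_len(n_points) - 1) * interval_min
  loss <- stomatal_rate * pmin(times, closure_time_min) +
    cuticular_rate * pmax(times - closure_time_min, 0)
  mass <- sm_g - loss
  if (noise_sd > 0) mass <- mass + stats::rnorm(n_points, 0, noise_sd)
  mass <- pmin(cummin(mass), sm_g)
  mass <- pmax(mass, dm_g)
  drying_curve(leaf_id, times, mass, sm_g, dm_g, leaf_area_m2, env)
}

#' Simulate gene models along synthetic chromosomes
#'
#' Genes of 1.5-4 kb with 2-4 CDS intervals are placed on `n_chrom`
#' chromosomes with intergenic gaps large enough (> 12 kb) that 5 kb flanked
#' regions of neighbouring genes do not overlap. Strands alternate.
#'
#' @param n_genes Number of genes.
#' @param n_chrom Number of chromosomes to spread them over.
#' @param seed Integer seed.
#' @return Object of class `gene_models`: list with `genes` (data frame:
#'   `gene_id`, `chrom`, `start`, `end`, `strand`) and `cds` (data frame:
#'   `gene_id`, `start`, `end`).
#' @export
simulate_gene_models <- function(n_genes = 100, n_chrom = 2, seed = 1) {
  if (n_genes < 1) stop("need >= 1 gene")
  set.seed(seed)
  chrom_of <- rep(paste0("chr", seq_len(n_chrom)), length.out = n_genes)
  chrom_of <- sort(chrom_of)
  genes <- vector("list", n_genes)
  cds <- vector("list", n_genes)
  pos <- stats::setNames(rep(20000L, n_chrom), paste0("chr", seq_len(n_chrom)))
  for (i in seq_len(n_genes)) {
    ch <- chrom_of[i]
    len <- sample(1500:4000, 1)
    start <- pos[[ch]]
    end <- start + len - 1L
    n_cds <- sample(2:4, 1)
    ## cut [start, end] into 2*n_cds - 1 alternating exon/intron chunks
    cuts <- sort(sample(seq(start + 50L, end - 50L), 2L * n_cds - 2L))
    bounds <- c(start, cuts, end)
    cs <- bounds[seq(1, 2 * n_cds - 1, by = 2)]
    ce <- bounds[seq(2, 2 * n_cds, by = 2)]
    ce[n_cds] <- end
    gid <- sprintf("gene%03d", i)
    genes[[i]] <- data.frame(gene_id = gid, chrom = ch, start = start,
                             end = end,
                             strand = if (i %% 2 == 0) "-" else "+",
                             stringsAsFactors = FALSE)
    cds[[i]] <- data.frame(gene_id = gid, start = cs, end = ce,
                           stringsAsFactors = FALSE)
    pos[[ch]] <- end + sample(13000:20000, 1)
  }
  structure(list(genes = do.call(rbind, genes), cds = do.call(rbind, cds)),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d genes on %d chromosome(s), %d CDS intervals\n",
              nrow(x$genes), length(unique(x$genes$chrom)), nrow(x$cds)))
  invisible(x)
}

#' Write gene models to GFF3
#'
#' Emits `gene` and `CDS` features (1-based inclusive coordinates) readable by
#' [read_gene_models()].
#'
#' @param gene_models A [simulate_gene_models()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(gene_models, path) {
  g <- gene_models$genes
  cd <- merge(gene_models$cds, g[, c("gene_id", "chrom", "strand")],
              by = "gene_id")
  lines <- c("##gff-version 3",
             sprintf("%s\tcuticula\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     g$chrom, g$start, g$end, g$strand, g$gene_id),
             sprintf("%s\tcuticula\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
                     cd$chrom, cd$start, cd$end, cd$strand, cd$gene_id,
                     cd$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate tetraploid variants with planted ecotype differentiation
#'
#' Places `n_snps_per_gene` biallelic SNPs uniformly within the 5 kb-flanked
#' region of each gene. Each SNP gets a baseline alternate-allele frequency
#' drawn from Beta(`beta_a`, `beta_b`) (U-shaped by default, a proxy for an
#' outcrosser's site-frequency spectrum), shared by both ecotypes; for SNPs in
#' `selected_genes` the alpine frequency is shifted by `afd_shift` away from
#' the nearer frequency boundary (and clipped to \[0, 1\]), planting the
#' allele-frequency-difference signal the selection scan must find. Genotypes
#' are binomial allele dosages, Binomial(`ploidy`, p), per individual.
#'
#' @param design A [make_design()] object (supplies populations/ecotypes).
#' @param n_individuals_per_pop Sequenced individuals per population.
#' @param gene_models A [simulate_gene_models()] object.
#' @param n_snps_per_gene SNPs per flanked gene region.
#' @param selected_genes Character vector of gene ids carrying the planted
#'   shift (subset of the gene models).
#' @param afd_shift Planted alpine-vs-foothill frequency shift in \[0, 1\].
#' @param ploidy Genotype ploidy (default 4, autotetraploid).
#' @param beta_a,beta_b Beta parameters of the baseline frequency
#'   distribution (default 0.8, 0.8).
#' @param flank Flank width (bp) of the region SNPs are placed in.
#' @param seed Integer seed.
#' @return Object of class `variant_table`: list with `sites` (data frame:
#'   `chrom`, `pos`, `ref`, `alt`, `source_gene`, `freq_foothill_true`,
#'   `freq_alpine_true`), `dosage` (integer matrix, sites x individuals),
#'   `individuals` (data frame: `indiv_id`, `population`, `ecotype`,
#'   `region`), `ploidy`.
#' @export
simulate_variants <- function(design, n_individuals_per_pop = 10,
                              gene_models, n_snps_per_gene = 20,
                              selected_genes = character(), afd_shift = 0,
                              ploidy = 4, beta_a = 0.8, beta_b = 0.8,
                              flank = 5000, seed = 1) {
  stopifnot(inherits(design, "study_design"),
            inherits(gene_models, "gene_models"))
  if (afd_shift < 0 || afd_shift > 1) stop("afd_shift must be in [0, 1]")
  if (length(selected_genes) &&
      !all(selected_genes %in% gene_models$genes$gene_id))
    stop("selected_genes must be a subset of the gene models")
  set.seed(seed)
  pops <- design$populations
  ind <- do.call(rbind, lapply(seq_len(nrow(pops)), function(i) {
    data.frame(indiv_id = sprintf("%s_i%02d", pops$population[i],
                                  seq_len(n_individuals_per_pop)),
               population = pops$population[i], ecotype = pops$ecotype[i],
               region = pops$region[i], stringsAsFactors = FALSE)
  }))
  g <- gene_models$genes
  sites <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    lo <- max(1L, g$start[i] - as.integer(flank))
    hi <- g$end[i] + as.integer(flank)
    data.frame(chrom = g$chrom[i],
               pos = sort(sample(lo:hi, n_snps_per_gene)),
               source_gene = g$gene_id[i], stringsAsFactors = FALSE)
  }))
  sites <- sites[order(sites$chrom, sites$pos), ]
  sites <- sites[!duplicated(sites[, c("chrom", "pos")]), ]
  n_snp <- nrow(sites)
  bases <- c("A", "C", "G", "T")
  sites$ref <- sample(bases, n_snp, replace = TRUE)
  sites$alt <- vapply(sites$ref,
                      function(r) sample(setdiff(bases, r), 1), character(1))
  p0 <- stats::rbeta(n_snp, beta_a, beta_b)
  p_alp <- p0
  sel <- sites$source_gene %in% selected_genes
  if (afd_shift > 0 && any(sel)) {
    up <- p0[sel] + afd_shift <= 1
    p_alp[sel] <- ifelse(up, p0[sel] + afd_shift, p0[sel] - afd_shift)
    p_alp[sel] <- pmin(pmax(p_alp[sel], 0), 1)
  }
  sites$freq_foothill_true <- p0
  sites$freq_alpine_true <- p_alp
  p_mat <- cbind(foothill = p0, alpine = p_alp)
  dos <- matrix(0L, n_snp, nrow(ind),
                dimnames = list(NULL, ind$indiv_id))
  for (j in seq_len(nrow(ind))) {
    dos[, j] <- stats::rbinom(n_snp, ploidy, p_mat[, ind$ecotype[j]])
  }
  sites <- sites[, c("chrom", "pos", "ref", "alt", "source_gene",
                     "freq_foothill_true", "freq_alpine_true")]
  rownames(sites) <- NULL
  structure(list(sites = sites, dosage = dos, individuals = ind,
                 ploidy = as.integer(ploidy)),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("<variant_table> %d SNPs x %d individuals (ploidy %d)\n",
              nrow(x$sites), ncol(x$dosage), x$ploidy))
  invisible(x)
}

dosage_to_gt <- function(d, ploidy) {
  if (is.na(d)) return(paste(rep(".", ploidy), collapse = "/"))
  paste(c(rep("0", ploidy - d), rep("1", d)), collapse = "/")
}

#' Write a variant table as VCF v4.2 with polyploid GT fields
#'
#' Integer allele dosages are written as unphased genotypes with `ploidy`
#' alleles (dosage 2 at ploidy 4 becomes `0/0/1/1`); missing dosages become
#' `./././.`. The output round-trips through [read_vcf_dosage()] with
#' identical dosages.
#'
#' @param variants A `variant_table`.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path) {
  stopifnot(inherits(variants, "variant_table"))
  s <- variants$sites
  gt <- apply(variants$dosage, c(1, 2), dosage_to_gt,
              ploidy = variants$ploidy)
  contigs <- unique(s$chrom)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=cuticula",
    sprintf("##contig=<ID=%s>", contigs),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(variants$dosage)), collapse = "\t"))
  body <- paste(s$chrom, s$pos, sprintf("snp%05d", seq_len(nrow(s))),
                s$ref, s$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' The default GC-MS wax compound panel
#'
#' Twenty-nine identified cuticular wax compounds spanning the classes seen in
#' rosette-leaf waxes of *Arabidopsis* species: n-alkanes (C29, C31, C33
#' dominant), iso-branched alkanes (C29, C31), primary alcohols (1-hexacosanol
#' and 1-octacosanol most abundant), free fatty acids (including linoleic
#' acid), aldehydes, alkyl esters and a ketone. Baseline surface
#' concentrations (`base_nmol_cm2`) are loosely realistic relative
#' abundances; retention times follow chain length on a 5%-phenyl column ramp.
#'
#' @return Data frame: `compound`, `class`, `chain_length`, `rt_min`,
#'   `base_nmol_cm2`.
#' @export
default_wax_compounds <- function() {
  d <- rbind(
    data.frame(compound = c("pentacosane", "heptacosane", "nonacosane",
                            "hentriacontane", "tritriacontane"),
               class = "alkane", chain_length = c(25, 27, 29, 31, 33),
               base_nmol_cm2 = c(0.08, 0.25, 2.5, 3.0, 1.2)),
    data.frame(compound = c("iso-nonacosane", "iso-hentriacontane"),
               class = "iso-alkane", chain_length = c(29, 31),
               base_nmol_cm2 = c(0.30, 0.35)),
    data.frame(compound = c("1-docosanol", "1-tetracosanol", "1-hexacosanol",
                            "1-octacosanol", "1-triacontanol",
                            "1-dotriacontanol"),
               class = "primary alcohol", chain_length = c(22, 24, 26, 28, 30,
                                                           32),
               base_nmol_cm2 = c(0.05, 0.15, 1.0, 0.8, 0.2, 0.05)),
    data.frame(compound = c("palmitic acid", "linoleic acid", "oleic acid",
                            "stearic acid", "arachidic acid", "behenic acid",
                            "lignoceric acid", "cerotic acid",
                            "montanic acid"),
               class = "fatty acid", chain_length = c(16, 18, 18, 18, 20, 22,
                                                      24, 26, 28),
               base_nmol_cm2 = c(0.40, 0.30, 0.25, 0.35, 0.10, 0.12, 0.15,
                                 0.20, 0.08)),
    data.frame(compound = c("hexacosanal", "octacosanal", "triacontanal"),
               class = "aldehyde", chain_length = c(26, 28, 30),
               base_nmol_cm2 = c(0.12, 0.18, 0.10)),
    data.frame(compound = c("tetracontanyl ester", "dotetracontanyl ester",
                            "tetratetracontanyl ester"),
               class = "ester", chain_length = c(40, 42, 44),
               base_nmol_cm2 = c(0.06, 0.05, 0.04)),
    data.frame(compound = "nonacosan-15-one", class = "ketone",
               chain_length = 29, base_nmol_cm2 = 0.07))
  ## retention time roughly linear in carbon number on the ramp, with small
  ## class offsets (silylated alcohols/acids elute slightly later than the
  ## alkane of equal carbon count)
  offset <- c(alkane = 0, `iso-alkane` = -0.25, `primary alcohol` = 0.35,
              `fatty acid` = 0.55, aldehyde = 0.15, ester = 0.2, ketone = 0.3)
  d$rt_min <- 19 + (d$chain_length - 20) * 0.55 + offset[d$class]
  rownames(d) <- NULL
  d
}

#' Default n-alkane ladder for retention-index calibration
#'
#' @param carbons Carbon numbers of the co-injected n-alkanes.
#' @return Data frame `carbon`, `rt_min`, strictly increasing.
#' @export
default_alkane_ladder <- function(carbons = seq(20, 46, by = 2)) {
  data.frame(carbon = carbons, rt_min = 19 + (carbons - 20) * 0.55)
}

#' Simulate a GC-MS peak table with planted ecotype fold-changes
#'
#' Per-sample wax surface concentrations are log-normal around the compound
#' baseline, with a population-level random intercept (SD `pop_sd` on the
#' natural-log scale, drawn per population and compound) matching the
#' random-intercept structure the per-compound tests fit, multiplied by
#' `fold_changes[compound]` for alpine samples. Detector response is a
#' per-sample log-normal gain applied equally to all peaks and to the internal
#' standard, so the internal-standard ratio is gain-free by construction. Wax
#' sampling happens in the alpine common garden only, matching the field
#' protocol.
#'
#' @param design A [make_design()] object.
#' @param compounds Compound panel as from [default_wax_compounds()].
#' @param is_amount_nmol Internal standard amount per sample (default 10 nmol
#'   = 10 ul of 1 mM tetracosane).
#' @param fold_changes Named numeric vector of alpine/foothill concentration
#'   ratios; compounds not named get 1.
#' @param lognormal_sd SD of the log-normal biological noise on
#'   concentrations (natural-log scale).
#' @param pop_sd SD of the population random intercept on ln concentration
#'   (default 0.1).
#' @param samples_per_population Pooled-leaf samples per population
#'   (default 9).
#' @param leaf_area_mean_cm2,leaf_area_sd_cm2 Leaf area distribution of the
#'   pooled samples (defaults 2.16 and 0.44 cm^2).
#' @param seed Integer seed.
#' @return Long-format data frame (class `peak_table`): `sample_id`,
#'   `population`, `ecotype`, `region`, `compound`, `class`, `chain_length`,
#'   `rt_min`, `peak_area`, `is_area`, `is_amount_nmol`, `leaf_area_cm2`.
#' @export
simulate_peak_table <- function(design, compounds = default_wax_compounds(),
                                is_amount_nmol = 10, fold_changes = NULL,
                                lognormal_sd = 0.3, pop_sd = 0.1,
                                samples_per_population = 9,
                                leaf_area_mean_cm2 = 2.16,
                                leaf_area_sd_cm2 = 0.44, seed = 1) {
  stopifnot(inherits(design, "study_design"))
  if (is_amount_nmol <= 0) stop("internal standard amount must be positive")
  if (any(compounds$base_nmol_cm2 <= 0)) stop("baseline areas must be positive")
  set.seed(seed)
  pops <- design$populations
  fc <- stats::setNames(rep(1, nrow(compounds)), compounds$compound)
  if (!is.null(fold_changes)) {
    bad <- setdiff(names(fold_changes), compounds$compound)
    if (length(bad)) stop("fold_changes for unknown compounds: ",
                          paste(bad, collapse = ", "))
    fc[names(fold_changes)] <- fold_changes
  }
  pop_int <- matrix(stats::rnorm(nrow(pops) * nrow(compounds), 0, pop_sd),
                    nrow(pops), nrow(compounds))
  rows <- vector("list", nrow(pops) * samples_per_population)
  k <- 0
  for (i in seq_len(nrow(pops))) {
    alpine <- pops$ecotype[i] == "alpine"
    for (s in seq_len(samples_per_population)) {
      k <- k + 1
      la <- max(0.5, stats::rnorm(1, leaf_area_mean_cm2, leaf_area_sd_cm2))
      gain <- 1000 * exp(stats::rnorm(1, 0, 0.2))
      conc <- compounds$base_nmol_cm2 * (if (alpine) fc[compounds$compound]
                                         else 1) *
        exp(pop_int[i, ] + stats::rnorm(nrow(compounds), 0, lognormal_sd))
      rows[[k]] <- data.frame(
        sample_id = sprintf("%s_s%02d", pops$population[i], s),
        population = pops$population[i], ecotype = pops$ecotype[i],
        region = pops$region[i], compound = compounds$compound,
        class = compounds$class, chain_length = compounds$chain_length,
        rt_min = compounds$rt_min,
        peak_area = gain * conc * la,
        is_area = gain * is_amount_nmol,
        is_amount_nmol = is_amount_nmol, leaf_area_cm2 = la,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Simulate an RNA-seq count matrix with planted ecotype fold-changes
#'
#' One sample per population per growth condition. Counts are negative
#' binomial with mean `lib_factor * base_mean * 2^(lfc * alpine) *
#' 2^(condition_lfc * condition2)` and gene-wise dispersion `dispersion`
#' (Poisson when 0).
#'
#' @param design A [make_design()] object.
#' @param n_genes Number of genes.
#' @param de_genes Character vector of gene ids with a planted ecotype
#'   log2 fold-change.
#' @param lfc Planted log2 fold-change (alpine vs foothill) for `de_genes`
#'   (scalar, or named vector over `de_genes`).
#' @param dispersion Negative-binomial dispersion (>= 0; 0 gives Poisson).
#' @param n_conditions Number of growth conditions (default 2).
#' @param condition_lfc Per-gene log2 shift between conditions (scalar or
#'   length-`n_genes` vector; default 0).
#' @param base_mean_log_mu,base_mean_log_sd Log-normal parameters of the
#'   per-gene baseline mean count.
#' @param seed Integer seed.
#' @return List (class `sim_counts`): `counts` (integer matrix genes x
#'   samples), `samples` (data frame: `sample_id`, `population`, `ecotype`,
#'   `region`, `condition`), `de_genes`, `lfc`.
#' @export
simulate_counts <- function(design, n_genes = 1000, de_genes = character(),
                            lfc = 0, dispersion = 0.1, n_conditions = 2,
                            condition_lfc = 0, base_mean_log_mu = log(300),
                            base_mean_log_sd = 1, seed = 1) {
  stopifnot(inherits(design, "study_design"))
  if (dispersion < 0) stop("dispersion must be >= 0")
  genes <- sprintf("g%04d", seq_len(n_genes))
  if (length(de_genes) && !all(de_genes %in% genes))
    stop("de_genes must be a subset of the simulated genes")
  set.seed(seed)
  pops <- design$populations
  samples <- expand.grid(condition = paste0("cond", seq_len(n_conditions)),
                         population = pops$population,
                         stringsAsFactors = FALSE)
  samples <- merge(samples, pops[, c("population", "ecotype", "region")],
                   by = "population")
  samples$sample_id <- sprintf("%s_%s", samples$population, samples$condition)
  samples <- samples[order(samples$sample_id),
                     c("sample_id", "population", "ecotype", "region",
                       "condition")]
  rownames(samples) <- NULL
  base_mean <- exp(stats::rnorm(n_genes, base_mean_log_mu, base_mean_log_sd))
  lfc_vec <- stats::setNames(rep(0, n_genes), genes)
  if (length(de_genes)) {
    v <- if (!is.null(names(lfc))) lfc[de_genes] else rep_len(lfc,
                                                              length(de_genes))
    lfc_vec[de_genes] <- v
  }
  cond_vec <- rep_len(condition_lfc, n_genes)
  lib <- exp(stats::rnorm(nrow(samples), 0, 0.15))
  counts <- matrix(0L, n_genes, nrow(samples),
                   dimnames = list(genes, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    alp <- as.numeric(samples$ecotype[j] == "alpine")
    c2 <- as.numeric(samples$condition[j] != "cond1")
    mu <- lib[j] * base_mean * 2^(lfc_vec * alp) * 2^(cond_vec * c2)
    counts[, j] <- if (dispersion == 0) stats::rpois(n_genes, mu)
    else stats::rnbinom(n_genes, mu = mu, size = 1 / dispersion)
  }
  structure(list(counts = counts, samples = samples, de_genes = de_genes,
                 lfc = lfc), class = "sim_counts")
}
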