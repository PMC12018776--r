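# Synthetic-data generators: design layout, determinism, round trips,
# planted-signal structure.

test_that("study design lays out regions x ecotypes x populations", {
  d <- make_design(3, 1, 14, seed = 1)
  expect_equal(nrow(d$populations), 6)
  expect_equal(d$leaves_per_population, 14)
  expect_setequal(unique(d$populations$ecotype), c("foothill", "alpine"))
  expect_equal(d$gardens, c("foothill", "alpine"))

  d_min <- make_design(1, 1, 1, seed = 0)
  expect_equal(nrow(d_min$populations), 2)

  d12 <- make_design(3, 2, 5, seed = 7)
  expect_equal(nrow(d12$populations), 12)
  expect_false(anyDuplicated(d12$populations$population) > 0)

  expect_error(make_design(0, 1, 1), ">= 1")
})

test_that("generators are seed-deterministic", {
  expect_identical(make_design(3, 2, 14, seed = 5),
                   make_design(3, 2, 14, seed = 5))
  d <- make_design(2, 1, 4, seed = 1)
  expect_identical(simulate_traits(d, seed = 3), simulate_traits(d, seed = 3))
  gm <- simulate_gene_models(10, seed = 2)
  expect_identical(gm, simulate_gene_models(10, seed = 2))
  expect_identical(simulate_variants(d, 3, gm, 5, seed = 4),
                   simulate_variants(d, 3, gm, 5, seed = 4))
  expect_identical(simulate_peak_table(d, seed = 6),
                   simulate_peak_table(d, seed = 6))
  sc <- simulate_counts(d, 50, seed = 8)
  expect_identical(sc$counts, simulate_counts(d, 50, seed = 8)$counts)
})

test_that("degenerate noise gives identical leaves; values stay physical", {
  d <- make_design(2, 1, 3, seed = 1)
  tr <- simulate_traits(d, sigma_pop = 0, sigma_resid = 0, seed = 1)
  expect_equal(length(unique(tr$gmin_m_s)), 1)
  expect_equal(length(unique(tr$wsd_pct)), 1)

  tr2 <- simulate_traits(make_design(3, 2, 10, seed = 2), sigma_resid = 1,
                         seed = 2)
  expect_true(all(tr2$gmin_m_s > 0))
  expect_true(all(tr2$wsd_pct >= 0 & tr2$wsd_pct <= 100))
  expect_true(all(tr2$theta_adaxial > 0 & tr2$theta_adaxial < 180))
  expect_error(simulate_traits(d, sigma_pop = -1), ">= 0")
})

test_that("planted ecotype effect on ln g_min is recovered by the LMM", {
  d <- make_design(3, 2, 40, seed = 11)
  tr <- simulate_traits(d, fixed_effects = list(gmin = list(ecotype = -0.5)),
                        sigma_pop = 0.05, sigma_resid = 0.3, seed = 11)
  fit <- fit_trait_lmm(tr, "gmin_m_s", "ln")
  fe <- lme4::fixef(fit$model)
  # sum-to-zero coding with levels (alpine, foothill): ecotype1 codes alpine,
  # so the alpine - foothill difference is 2 * ecotype1
  expect_identical(levels(fit$data$ecotype)[1], "alpine")
  expect_equal(2 * fe[["ecotype1"]], -0.5, tolerance = 0.15)
})

test_that("without population variance, Satterthwaite df approach residual df", {
  d <- make_design(3, 2, 10, seed = 3)
  tr <- simulate_traits(d, sigma_pop = 0, sigma_resid = 0.4, seed = 3)
  fit <- suppressMessages(fit_trait_lmm(tr, "gmin_m_s", "ln"))
  a <- anova_type3(fit)
  resid_df <- fit$n_used - length(lme4::fixef(fit$model))
  expect_gt(a$dendf[a$term == "ecotype"], 0.9 * resid_df)
})

test_that("drying-curve generator honours the biphasic protocol", {
  cv <- simulate_drying_curve(1e-3, 0.3, 0.1, 1e-3, 0, closure_time_min = 90,
                              interval_min = 30, n_points = 6, seed = 1)
  expect_equal(cv$times_min, seq(0, 150, by = 30))
  # zero cuticular rate: constant mass after closure
  m <- cv$masses_g
  expect_equal(m[4], m[5])
  expect_equal(m[5], m[6])
  # noisy curves stay monotone and above dry mass
  cvn <- simulate_drying_curve(1e-3, 0.12, 0.1, 1e-3, 1e-5, noise_sd = 5e-3,
                               seed = 9)
  expect_true(all(diff(cvn$masses_g) <= 0))
  expect_true(all(cvn$masses_g >= cvn$dm_g))
  expect_error(simulate_drying_curve(1e-3, 0.1, 0.2, 1e-3, 1e-5), "SM > DM")
  expect_error(simulate_drying_curve(1e-3, 0.3, 0.1, 1e-5, 1e-3),
               "stomatal_rate > cuticular_rate")
})

test_that("variant generator plants the requested frequency structure", {
  d <- make_design(1, 1, 1, seed = 1)
  gm <- simulate_gene_models(20, seed = 1)

  # binomial dosage mean: p ~ 0.5 at ploidy 4 -> mean dosage ~ 2
  vt <- simulate_variants(d, n_individuals_per_pop = 400, gm, 5,
                          beta_a = 1e6, beta_b = 1e6, seed = 2)
  expect_equal(mean(vt$dosage), 2, tolerance = 0.05)

  # null: no planted shift -> alpine and foothill frequencies identical
  expect_equal(vt$sites$freq_alpine_true, vt$sites$freq_foothill_true)

  # planted shift realizes AFD ~ 0.5 in selected genes
  sel <- gm$genes$gene_id[1:5]
  vt2 <- simulate_variants(d, 10, gm, 10, selected_genes = sel,
                           afd_shift = 0.5, seed = 3)
  planted <- vt2$sites$source_gene %in% sel
  expect_equal(abs(vt2$sites$freq_alpine_true -
                     vt2$sites$freq_foothill_true)[planted],
               rep(0.5, sum(planted)), tolerance = 1e-12)
  expect_true(all(vt2$sites$freq_alpine_true >= 0 &
                    vt2$sites$freq_alpine_true <= 1))

  expect_error(simulate_variants(d, 2, gm, 2, afd_shift = 1.5), "\\[0, 1\\]")
  expect_error(simulate_variants(d, 2, gm, 2, selected_genes = "nope",
                                 afd_shift = 0.1), "subset")
})

test_that("VCF writer round-trips dosages bit-identically", {
  d <- make_design(2, 1, 1, seed = 1)
  gm <- simulate_gene_models(5, seed = 1)
  vt <- simulate_variants(d, 4, gm, 8, seed = 5)
  vt$dosage[2, 3] <- NA  # exercise missing genotypes
  f <- tempfile(fileext = ".vcf")
  write_vcf(vt, f)
  got <- read_vcf_dosage(f, metadata = vt$individuals)
  expect_identical(unname(got$dosage), unname(vt$dosage))
  expect_identical(got$ploidy, vt$ploidy)
  expect_identical(got$sites$pos, vt$sites$pos)
  expect_identical(got$sites$ref, vt$sites$ref)
  expect_identical(got$individuals$ecotype, vt$individuals$ecotype)
})

test_that("GFF3 writer round-trips gene models", {
  gm <- simulate_gene_models(8, n_chrom = 2, seed = 4)
  f <- tempfile(fileext = ".gff3")
  write_gff3(gm, f)
  got <- read_gene_models(f)
  expect_equal(got$genes[, names(gm$genes)], gm$genes)
  cmp <- function(x) x[order(x$gene_id, x$start), c("gene_id", "start", "end")]
  expect_equal(cmp(got$cds), cmp(gm$cds), ignore_attr = TRUE)
  # CDS contained in gene span
  m <- merge(gm$cds, gm$genes, by = "gene_id", suffixes = c("", ".g"))
  expect_true(all(m$start >= m$start.g & m$end <= m$end.g))
})

test_that("peak-table generator applies exact fold changes when noise-free", {
  d <- make_design(3, 2, 1, seed = 1)
  pk <- simulate_peak_table(d, fold_changes = c(`1-hexacosanol` = 2),
                            lognormal_sd = 0, pop_sd = 0,
                            samples_per_population = 2, seed = 1)
  norm <- normalize_peaks(pk)
  hex <- norm[norm$compound == "1-hexacosanol", ]
  ratio <- median(hex$abundance_nmol_cm2[hex$ecotype == "alpine"]) /
    median(hex$abundance_nmol_cm2[hex$ecotype == "foothill"])
  expect_equal(ratio, 2, tolerance = 1e-12)
  # untouched compound: ratio exactly 1
  alk <- norm[norm$compound == "nonacosane", ]
  expect_equal(median(alk$abundance_nmol_cm2[alk$ecotype == "alpine"]) /
                 median(alk$abundance_nmol_cm2[alk$ecotype == "foothill"]), 1)
  expect_error(simulate_peak_table(d, fold_changes = c(nothere = 2)),
               "unknown compound")
})

test_that("count generator reduces to Poisson at zero dispersion", {
  d <- make_design(3, 1, 1, seed = 1)
  sc <- simulate_counts(d, 2000, dispersion = 0, base_mean_log_sd = 0,
                        seed = 2)
  # within a sample all genes share one mean: variance ~ mean (Poisson)
  ratio <- apply(sc$counts, 2, function(x) stats::var(x) / mean(x))
  expect_true(all(ratio > 0.85 & ratio < 1.15))
  expect_error(simulate_counts(d, 10, de_genes = "zzz", lfc = 2), "subset")
  expect_error(simulate_counts(d, 10, dispersion = -1), ">= 0")
})
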