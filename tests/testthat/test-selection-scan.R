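# AFD selection scan: frequencies, outlier calling, gene mapping, densities,
# candidate selection, coding effects.

test_that("pooled tetraploid allele frequencies", {
  dos <- matrix(c(4, 4, 4, 4,
                  0, 2, 4, 2,
                  0, 0, 0, 0), nrow = 3, byrow = TRUE)
  vt <- toy_variants(dos, ecotypes = c("alpine", "alpine", "alpine",
                                       "foothill"))
  fa <- ecotype_allele_frequency(vt, "alpine")
  expect_equal(fa, c(1, 0.5, 0))  # {0,2,4} at ploidy 4 -> 6/12
  expect_error(ecotype_allele_frequency(vt, "subalpine"), "unknown group")

  # all-missing SNP in a group yields NA and is dropped by the scan
  dos2 <- dos
  dos2[2, 1:3] <- NA
  vt2 <- toy_variants(dos2, c("alpine", "alpine", "alpine", "foothill"))
  expect_true(is.na(ecotype_allele_frequency(vt2, "alpine")[2]))
})

test_that("pooled frequency equals mean per-population frequency when balanced", {
  set.seed(5)
  d <- make_design(3, 2, 1, seed = 5)
  gm <- simulate_gene_models(5, seed = 5)
  vt <- simulate_variants(d, n_individuals_per_pop = 6, gm, 10, seed = 5)
  expect_equal(ecotype_allele_frequency(vt, "alpine"),
               ecotype_allele_frequency(vt, "alpine", per_population = TRUE),
               tolerance = 1e-12)
})

test_that("AFD is an absolute, symmetric, relabelling-invariant difference", {
  expect_equal(allele_freq_difference(0.8, 0.3), 0.5)
  expect_equal(allele_freq_difference(0.3, 0.8), 0.5)
  expect_equal(allele_freq_difference(0.5, 0.5), 0)
  expect_equal(allele_freq_difference(1, 0), 1)
  expect_error(allele_freq_difference(1.2, 0), "\\[0, 1\\]")
  # relabelling ref/alt flips both frequencies: AFD unchanged
  f1 <- c(0.1, 0.7, 0.4)
  f2 <- c(0.9, 0.2, 0.4)
  expect_equal(allele_freq_difference(1 - f1, 1 - f2),
               allele_freq_difference(f1, f2))
})

test_that("outlier cut-off flags ceil(fraction x n) SNPs up to ties", {
  set.seed(11)
  afd <- stats::runif(1000)
  out <- afd_outliers(afd, 0.003)
  expect_equal(out$n_flagged, 3)  # ceil(0.003 * 1000), distinct values
  expect_true(all(afd[out$flags] >= out$threshold))
  expect_equal(sum(afd >= out$threshold), 3)
  # ties at the threshold are all included
  afd2 <- c(rep(0.9, 5), stats::runif(995, max = 0.5))
  expect_equal(afd_outliers(afd2, 0.003)$n_flagged, 5)
  # degenerate: everything tied
  expect_warning(all_tied <- afd_outliers(rep(0.2, 10), 0.1), "tied")
  expect_equal(all_tied$n_flagged, 10)
  expect_equal(afd_outliers(afd, 1)$n_flagged, 1000)
  expect_error(afd_outliers(numeric(0)), "no SNPs")
})

test_that("SNP-to-gene mapping respects flanks, strand and CDS boundaries", {
  genes <- data.frame(
    gene_id = c("gplus", "gminus"), chrom = "chr1",
    start = c(20000, 100000), end = c(22999, 102999),
    strand = c("+", "-"), stringsAsFactors = FALSE)
  cds <- data.frame(gene_id = c("gplus", "gplus", "gminus"),
                    start = c(20000, 22000, 100500),
                    end = c(20500, 22999, 101000))
  gm <- toy_genes(genes, cds)
  pos <- c(19999,   # start - 1 on + strand: upstream
           20250,   # inside first CDS: coding
           21000,   # between CDS: intron/UTR
           27999,   # end + 5000: assigned downstream
           28000,   # end + 5001: not assigned
           99999,   # just left of the minus-strand gene: downstream
           103200,  # just right of it: upstream
           50000)   # intergenic: unassigned
  dos <- matrix(2L, length(pos), 2)
  vt <- toy_variants(dos, c("alpine", "foothill"), pos = pos)
  asn <- map_snps_to_genes(vt, gm, flank = 5000)
  lookup <- function(i) asn[asn$snp_idx == i, ]
  expect_equal(lookup(1)$region_class, "upstream")
  expect_equal(lookup(2)$region_class, "coding")
  expect_equal(lookup(3)$region_class, "intron/UTR")
  expect_equal(lookup(4)$region_class, "downstream")
  expect_equal(nrow(lookup(5)), 0)
  expect_equal(lookup(6)$region_class, "downstream")
  expect_equal(lookup(6)$gene_id, "gminus")
  expect_equal(lookup(7)$region_class, "upstream")
  expect_equal(nrow(lookup(8)), 0)
  # chromosome mismatch: no assignment
  vt$sites$chrom <- "chr9"
  expect_equal(nrow(suppressWarnings(map_snps_to_genes(vt, gm, 5000))), 0)
})

test_that("outlier density per gene uses the flanked length in kb", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      start = c(6000, 50000), end = c(7999, 51999),
                      strand = "+", stringsAsFactors = FALSE)
  gm <- toy_genes(genes, data.frame(gene_id = character(0), start = integer(0),
                                    end = integer(0)))
  pos <- c(6100, 6200, 6300)
  vt <- toy_variants(matrix(2L, 3, 2), c("alpine", "foothill"), pos = pos)
  asn <- map_snps_to_genes(vt, gm, flank = 5000)
  # flanked g1: 1000..12999 = 12 kb; two of three SNPs flagged
  dens <- gene_outlier_density(asn, c(TRUE, TRUE, FALSE), gm, flank = 5000)
  expect_equal(dens$length_kb[dens$gene_id == "g1"], 12)
  expect_equal(dens$density_per_kb[dens$gene_id == "g1"], 2 / 12,
               tolerance = 1e-12)
  expect_equal(dens$n_outliers[dens$gene_id == "g2"], 0)
  expect_true(dens$no_data[dens$gene_id == "g2"])
  # widening the flank with no new SNPs strictly lowers the density
  asn2 <- map_snps_to_genes(vt, gm, flank = 10000)
  dens2 <- gene_outlier_density(asn2, c(TRUE, TRUE, FALSE), gm, flank = 10000)
  expect_lt(dens2$density_per_kb[1], dens$density_per_kb[1])
})

test_that("candidate selection keeps the densest outlier-carrying genes", {
  dens <- data.frame(gene_id = paste0("g", 1:4), n_snps = c(5, 5, 5, 5),
                     n_outliers = c(3, 2, 1, 0), length_kb = rep(10, 4),
                     density_per_kb = c(0.5, 0.2, 0.1, 0),
                     no_data = rep(FALSE, 4))
  got <- select_candidates(dens, 0.5)
  expect_equal(got$gene_id[got$candidate], c("g1", "g2"))
  # zero-outlier genes are never candidates
  dens0 <- dens
  dens0$n_outliers <- 0
  dens0$density_per_kb <- 0
  expect_false(any(select_candidates(dens0, 0.5)$candidate))
  expect_error(select_candidates(dens[0, ], 0.5), "empty")
})

test_that("coding effects translate the affected codon on either strand", {
  # plus strand, single CDS: ATG CTA GGG TAA
  gplus <- list(gene_id = "gp", strand = "+")
  cds_iv <- data.frame(start = 101, end = 112)
  seq <- "ATGCTAGGGTAA"
  # third-position wobble CTA -> CTG: synonymous (Leu)
  syn <- coding_effect(106, "A", "G", gplus, cds_iv, seq)
  expect_equal(syn$effect, "synonymous")
  expect_equal(syn$aa_ref, "L")
  # start codon ATG -> ATA: M -> I
  chg <- coding_effect(103, "G", "A", gplus, cds_iv, seq)
  expect_equal(chg$effect, "amino-acid-changing")
  expect_equal(c(chg$aa_ref, chg$aa_alt), c("M", "I"))

  # the same construction placed on the minus strand gives the same calls:
  # genomic sequence is the reverse complement, SNP positions mirrored
  gminus <- list(gene_id = "gm", strand = "-")
  # transcript position of genomic pos p is total - (p - start): pos 106
  # (wobble) maps to genomic 107 on the mirrored gene; alleles complemented
  syn2 <- coding_effect(107, "T", "C", gminus, cds_iv, seq)
  expect_equal(syn2$effect, "synonymous")
  expect_equal(syn2$cds_pos, syn$cds_pos)
  chg2 <- coding_effect(110, "C", "T", gminus, cds_iv, seq)
  expect_equal(chg2$effect, "amino-acid-changing")
  expect_equal(c(chg2$aa_ref, chg2$aa_alt), c("M", "I"))

  # spliced, two CDS intervals: same codons split across an intron
  cds_2 <- data.frame(start = c(101, 120), end = c(105, 126))
  spl <- coding_effect(121, "G", "A", gplus, cds_2, seq)  # CDS pos 7
  expect_equal(spl$cds_pos, 7)
  expect_equal(spl$codon_ref, "GGG")

  # guards
  expect_error(coding_effect(99, "A", "G", gplus, cds_iv, seq), "CDS interval")
  expect_error(coding_effect(103, "G", "A", gplus,
                             data.frame(start = 101, end = 111),
                             substr(seq, 1, 11)), "multiple of 3")
  expect_error(coding_effect(103, "C", "A", gplus, cds_iv, seq),
               "does not match")
})

test_that("full scan is deterministic and recovers planted genes", {
  d <- make_design(2, 1, 2, seed = 6)
  gm <- simulate_gene_models(30, seed = 6)
  sel <- gm$genes$gene_id[1:5]
  vt <- simulate_variants(d, 15, gm, 60, selected_genes = sel,
                          afd_shift = 0.5, seed = 6)
  sc1 <- suppressMessages(run_selection_scan(vt, gm))
  sc2 <- suppressMessages(run_selection_scan(vt, gm))
  expect_identical(sc1$snps, sc2$snps)
  expect_identical(sc1$genes, sc2$genes)
  # flagged count respects the ceiling rule (ties can only add)
  k <- ceiling(0.003 * nrow(sc1$snps))
  expect_gte(sum(sc1$snps$outlier), k)
  # candidates are planted genes only: the planted AFD dwarfs drift
  cand <- sc1$genes$gene_id[sc1$genes$candidate]
  expect_true(all(cand %in% sel))
  expect_gte(length(cand), 3)
  # BED output is well-formed
  bed <- tempfile(fileext = ".bed")
  write_outlier_bed(sc1, bed)
  b <- utils::read.delim(bed, header = FALSE)
  expect_equal(nrow(b), sum(sc1$snps$outlier))
  expect_true(all(b$V3 == b$V2 + 1))
})
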