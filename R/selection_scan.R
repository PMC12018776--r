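## Targeted allele-frequency-difference selection scan over a defined gene
## set: per-SNP AFD between ecotypes, outlier calling, SNP-to-gene mapping
## with flanking regions, per-gene outlier density, candidate selection,
## coding-effect classification.

#' Read polyploid genotype dosages from a VCF
#'
#' Parses GT fields of any ploidy into integer alternate-allele dosages.
#' Multiallelic sites are dropped (with a message), since the allele-frequency
#' difference is defined per biallelic SNP.
#'
#' @param path VCF file (v4.2; plain or gzipped).
#' @param metadata Optional data frame mapping `indiv_id` to `population`,
#'   `ecotype`, `region`; matched to the VCF sample names.
#' @return A `variant_table` (see [simulate_variants()]).
#' @export
read_vcf_dosage <- function(path, metadata = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    message(sprintf("dropping %d multiallelic site(s)", sum(multi)))
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  alleles <- strsplit(gt, "[/|]")
  dos <- vapply(alleles, function(a) {
    if (!length(a) || anyNA(a) || all(a == ".")) NA_integer_
    else sum(a == "1")
  }, integer(1))
  dos <- matrix(dos, nrow = nrow(gt), dimnames = dimnames(gt))
  ploidy <- length(strsplit(gt[which(!is.na(gt) & !grepl("\\.", gt))[1]],
                            "[/|]")[[1]])
  ind <- data.frame(indiv_id = colnames(gt), stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    ind <- merge(ind, metadata, by = "indiv_id", sort = FALSE)
    if (nrow(ind) != ncol(gt))
      stop("metadata does not cover every VCF sample")
    ind <- ind[match(colnames(gt), ind$indiv_id), ]
  }
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  rownames(ind) <- NULL
  structure(list(sites = sites, dosage = dos, individuals = ind,
                 ploidy = as.integer(ploidy)),
            class = "variant_table")
}

#' Read gene models (gene spans + CDS intervals) from GFF3
#'
#' @param path GFF3 file with `gene` and `CDS` features; CDS features carry a
#'   `Parent` attribute naming their gene.
#' @return A `gene_models` object (see [simulate_gene_models()]).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gn <- gr[gr$type == "gene"]
  genes <- data.frame(gene_id = gn$ID,
                      chrom = as.character(GenomicRanges::seqnames(gn)),
                      start = GenomicRanges::start(gn),
                      end = GenomicRanges::end(gn),
                      strand = as.character(GenomicRanges::strand(gn)),
                      stringsAsFactors = FALSE)
  cd <- gr[gr$type == "CDS"]
  parent <- vapply(cd$Parent, function(p) as.character(p)[1], character(1))
  cds <- data.frame(gene_id = parent, start = GenomicRanges::start(cd),
                    end = GenomicRanges::end(cd), stringsAsFactors = FALSE)
  cds <- cds[order(cds$gene_id, cds$start), ]
  rownames(genes) <- rownames(cds) <- NULL
  structure(list(genes = genes, cds = cds), class = "gene_models")
}

#' Pooled ecotype allele frequency per SNP
#'
#' The alternate-allele frequency of a group is its dosage sum divided by
#' ploidy times the number of non-missing genotypes, pooling individuals of
#' the ecotype across populations and regions. SNPs with no non-missing
#' genotype in the group get `NA`.
#'
#' @param variants A `variant_table`.
#' @param group Ecotype label (a value of `individuals$ecotype`).
#' @param per_population If `TRUE`, return the unweighted mean of
#'   per-population frequencies instead of the pooled estimate.
#' @return Numeric vector of frequencies in \[0, 1\] (or `NA`).
#' @export
ecotype_allele_frequency <- function(variants, group,
                                     per_population = FALSE) {
  stopifnot(inherits(variants, "variant_table"))
  sel <- variants$individuals$ecotype == group
  if (!any(sel)) stop("unknown group label: ", group)
  freq_of <- function(cols) {
    d <- variants$dosage[, cols, drop = FALSE]
    nn <- rowSums(!is.na(d))
    f <- rowSums(d, na.rm = TRUE) / (variants$ploidy * nn)
    f[nn == 0] <- NA_real_
    f
  }
  if (!per_population) return(freq_of(sel))
  pops <- unique(variants$individuals$population[sel])
  fs <- vapply(pops, function(p)
    freq_of(sel & variants$individuals$population == p),
    numeric(nrow(variants$sites)))
  rowMeans(fs, na.rm = TRUE)
}

#' Allele frequency difference between two groups
#'
#' AFD = |f_a - f_f|, symmetric in its arguments and invariant to ref/alt
#' relabelling.
#'
#' @param freq_a,freq_b Frequencies in \[0, 1\].
#' @return AFD per SNP, in \[0, 1\].
#' @export
allele_freq_difference <- function(freq_a, freq_b) {
  if (any(stats::na.omit(c(freq_a, freq_b)) < 0) ||
      any(stats::na.omit(c(freq_a, freq_b)) > 1))
    stop("frequencies must be in [0, 1]")
  abs(freq_a - freq_b)
}

#' Flag outlier SNPs at an empirical AFD quantile cut-off
#'
#' The threshold is the AFD of the k-th most differentiated SNP, k =
#' ceiling(`top_fraction` x n), over the analysed SNP set; every SNP with AFD
#' at or above the threshold is flagged (ties are all included, so the flagged
#' count can exceed k).
#'
#' @param afd_values Numeric AFD vector (NA excluded from the ranking and
#'   never flagged).
#' @param top_fraction Outlier fraction (default 0.003, the 0.3% cut-off).
#' @return List: `threshold`, `flags` (logical vector), `n_flagged`.
#' @export
afd_outliers <- function(afd_values, top_fraction = 0.003) {
  ok <- !is.na(afd_values)
  n <- sum(ok)
  if (n == 0) stop("no SNPs to rank")
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must be in (0, 1]")
  k <- min(n, ceiling(top_fraction * n))
  thr <- sort(afd_values[ok], decreasing = TRUE)[k]
  flags <- !is.na(afd_values) & afd_values >= thr
  if (all(afd_values[ok] == afd_values[ok][1]))
    warning("all AFD values tied at the threshold; every SNP flagged")
  list(threshold = thr, flags = flags, n_flagged = sum(flags))
}

#' Map SNPs to flanked gene regions with region classes
#'
#' A SNP is assigned to every gene whose span extended by `flank` bp on both
#' sides (clipped at position 1) contains it; SNPs in overlapping flanks are
#' multiply assigned. The region class is `coding` if the position falls in a
#' CDS interval of that gene, `upstream`/`downstream` relative to the
#' unflanked gene span by strand, and `intron/UTR` otherwise.
#'
#' @param variants A `variant_table`.
#' @param gene_models A `gene_models` object.
#' @param flank Flank width in bp (default 5000). Boundaries inclusive.
#' @return Data frame: `snp_idx` (row in `variants$sites`), `gene_id`,
#'   `region_class`.
#' @export
map_snps_to_genes <- function(variants, gene_models, flank = 5000) {
  s <- variants$sites
  g <- gene_models$genes
  snp_gr <- GenomicRanges::GRanges(s$chrom,
                                   IRanges::IRanges(s$pos, s$pos))
  gene_gr <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(pmax(1L, g$start - as.integer(flank)),
                              g$end + as.integer(flank)))
  hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
  si <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  if (!length(si))
    return(data.frame(snp_idx = integer(0), gene_id = character(0),
                      region_class = character(0)))
  pos <- s$pos[si]
  cls <- character(length(si))
  before <- pos < g$start[gi]
  after <- pos > g$end[gi]
  plus <- g$strand[gi] == "+"
  cls[before & plus | after & !plus] <- "upstream"
  cls[after & plus | before & !plus] <- "downstream"
  inside <- !before & !after
  cls[inside] <- "intron/UTR"
  ## coding: CDS containment, per gene
  cds <- gene_models$cds
  for (k in which(inside)) {
    ci <- cds[cds$gene_id == g$gene_id[gi[k]], ]
    if (any(pos[k] >= ci$start & pos[k] <= ci$end)) cls[k] <- "coding"
  }
  multi <- sum(duplicated(si))
  if (multi > 0)
    message(sprintf("%d SNP(s) assigned to more than one gene", multi))
  data.frame(snp_idx = si, gene_id = g$gene_id[gi], region_class = cls,
             stringsAsFactors = FALSE)
}

#' Outlier SNP density per gene
#'
#' density = (number of flagged SNPs assigned to the gene) / (flanked region
#' length in kb). Genes with no assigned SNP at all get density 0 and a
#' `no_data` mark.
#'
#' @param assignments Output of [map_snps_to_genes()].
#' @param flags Logical outlier flags indexed like `variants$sites`.
#' @param gene_models The `gene_models` used for the assignment.
#' @param flank The flank width used (for the length denominator).
#' @return Data frame: `gene_id`, `n_snps`, `n_outliers`, `length_kb`,
#'   `density_per_kb`, `no_data`.
#' @export
gene_outlier_density <- function(assignments, flags, gene_models,
                                 flank = 5000) {
  g <- gene_models$genes
  len_kb <- (g$end + flank - pmax(1L, g$start - as.integer(flank)) + 1) / 1000
  n_snps <- as.integer(table(factor(assignments$gene_id,
                                    levels = g$gene_id)))
  out_tab <- table(factor(assignments$gene_id[flags[assignments$snp_idx]],
                          levels = g$gene_id))
  n_out <- as.integer(out_tab)
  data.frame(gene_id = g$gene_id, n_snps = n_snps, n_outliers = n_out,
             length_kb = len_kb, density_per_kb = n_out / len_kb,
             no_data = n_snps == 0, stringsAsFactors = FALSE)
}

#' Select candidate genes by outlier density
#'
#' Ranks the scanned genes (those with at least one assigned SNP) by outlier
#' SNP density, descending, and retains the top ceiling(`top_fraction` x n) of
#' them as candidates; ties at the boundary are all retained. Genes with zero
#' outlier SNPs are never candidates, so when outliers are concentrated in few
#' genes the candidate set is exactly the outlier-carrying genes (a scan
#' yielding outliers in 9 of 104 genes yields 9 candidates at fraction 0.5).
#'
#' @param densities Output of [gene_outlier_density()].
#' @param top_fraction Fraction of the scanned gene set eligible as
#'   candidates (default 0.5).
#' @return The `densities` data frame with an added logical `candidate`
#'   column.
#' @export
select_candidates <- function(densities, top_fraction = 0.5) {
  if (!nrow(densities)) stop("empty gene set")
  with_data <- !densities$no_data
  if (!any(with_data)) stop("no gene has assigned SNPs")
  nz <- densities$n_outliers > 0
  densities$candidate <- FALSE
  if (!any(nz)) return(densities)
  k <- ceiling(top_fraction * sum(with_data))
  thr <- sort(densities$density_per_kb[with_data], decreasing = TRUE)[k]
  densities$candidate <- nz & densities$density_per_kb >= max(thr, 1e-12)
  n_at <- sum(nz & densities$density_per_kb == thr)
  if (thr > 0 && sum(densities$candidate) > k)
    message(sprintf("boundary tie: %d gene(s) at the threshold density all retained",
                    n_at))
  densities
}

#' Classify a coding SNP as synonymous or amino-acid-changing
#'
#' Translates the codon containing the SNP for the reference and alternate
#' alleles using the standard nuclear genetic code. The spliced CDS sequence
#' must be supplied in transcript orientation (5' to 3' of the coding strand);
#' for minus-strand genes the genomic ref/alt alleles are complemented
#' internally.
#'
#' @param pos Genomic position (1-based) of the SNP.
#' @param ref,alt Reference and alternate alleles on the forward genomic
#'   strand (single bases).
#' @param gene A one-row data frame (or list) with `gene_id` and `strand`.
#' @param cds_intervals Data frame of this gene's CDS intervals (`start`,
#'   `end`, genomic coordinates, ascending).
#' @param cds_sequence The spliced CDS as a character string or
#'   [Biostrings::DNAString], transcript orientation, length divisible by 3.
#' @return List: `effect` (`"synonymous"` or `"amino-acid-changing"`),
#'   `codon_ref`, `codon_alt`, `aa_ref`, `aa_alt`, `cds_pos`.
#' @export
coding_effect <- function(pos, ref, alt, gene, cds_intervals, cds_sequence) {
  cds_intervals <- cds_intervals[order(cds_intervals$start), ]
  lens <- cds_intervals$end - cds_intervals$start + 1
  total <- sum(lens)
  if (total %% 3 != 0)
    stop("spliced CDS length is not a multiple of 3 (frame inconsistency)")
  hit <- which(pos >= cds_intervals$start & pos <= cds_intervals$end)
  if (!length(hit)) stop("SNP does not fall in a CDS interval")
  off_left <- sum(lens[seq_len(hit - 1)]) + (pos - cds_intervals$start[hit])
  minus <- identical(gene$strand, "-")
  t_pos <- if (minus) total - off_left else off_left + 1
  seq <- Biostrings::DNAString(as.character(cds_sequence))
  if (length(seq) != total)
    stop("CDS sequence length does not match the CDS intervals")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref_t <- if (minus) comp[[ref]] else ref
  alt_t <- if (minus) comp[[alt]] else alt
  if (as.character(seq[t_pos]) != ref_t)
    stop("reference allele does not match the CDS sequence at the SNP")
  codon_i <- (t_pos - 1) %/% 3
  codon_ref <- as.character(seq[(codon_i * 3 + 1):(codon_i * 3 + 3)])
  codon_alt <- codon_ref
  substr(codon_alt, t_pos - codon_i * 3, t_pos - codon_i * 3) <- alt_t
  ## no.init.codon: the codon is interior, not a translation start, so
  ## alternative initiator codons (CTG, TTG) must not be read as Met
  aa_ref <- as.character(Biostrings::translate(
    Biostrings::DNAString(codon_ref), no.init.codon = TRUE))
  aa_alt <- as.character(Biostrings::translate(
    Biostrings::DNAString(codon_alt), no.init.codon = TRUE))
  list(effect = if (aa_ref == aa_alt) "synonymous" else "amino-acid-changing",
       codon_ref = codon_ref, codon_alt = codon_alt,
       aa_ref = aa_ref, aa_alt = aa_alt, cds_pos = t_pos)
}

#' Run the full targeted selection scan
#'
#' Computes pooled alpine and foothill allele frequencies, per-SNP AFD over
#' the targeted gene regions, flags the top `top_snp_frac` most differentiated
#' SNPs, maps SNPs to flanked genes with region classes, computes per-gene
#' outlier densities and selects the top `top_gene_frac` of outlier-carrying
#' genes as candidates. SNPs with no data in either ecotype are dropped (with
#' a message).
#'
#' @param variants A `variant_table` with ecotype labels in `individuals`.
#' @param gene_models A `gene_models` object.
#' @param top_snp_frac SNP outlier fraction (default 0.003).
#' @param flank Flank width, bp (default 5000).
#' @param top_gene_frac Candidate-gene fraction among outlier-carrying genes
#'   (default 0.5).
#' @param per_population Use per-population-mean instead of pooled
#'   frequencies.
#' @return List (class `scan_result`): `snps` (per-SNP data frame with
#'   frequencies, AFD, outlier flag, assigned genes and region classes),
#'   `genes` (per-gene densities and candidate flags), `threshold`,
#'   `assignments`.
#' @export
run_selection_scan <- function(variants, gene_models, top_snp_frac = 0.003,
                               flank = 5000, top_gene_frac = 0.5,
                               per_population = FALSE) {
  fa <- ecotype_allele_frequency(variants, "alpine", per_population)
  ff <- ecotype_allele_frequency(variants, "foothill", per_population)
  keep <- !is.na(fa) & !is.na(ff)
  if (any(!keep))
    message(sprintf("dropping %d SNP(s) with no data in one ecotype",
                    sum(!keep)))
  vt <- variants
  vt$sites <- variants$sites[keep, , drop = FALSE]
  vt$dosage <- variants$dosage[keep, , drop = FALSE]
  fa <- fa[keep]
  ff <- ff[keep]
  afd <- allele_freq_difference(fa, ff)
  out <- afd_outliers(afd, top_snp_frac)
  asn <- map_snps_to_genes(vt, gene_models, flank)
  dens <- gene_outlier_density(asn, out$flags, gene_models, flank)
  dens <- select_candidates(dens, top_gene_frac)
  gene_of <- vapply(seq_len(nrow(vt$sites)), function(i) {
    paste(asn$gene_id[asn$snp_idx == i], collapse = ";")
  }, character(1))
  class_of <- vapply(seq_len(nrow(vt$sites)), function(i) {
    paste(asn$region_class[asn$snp_idx == i], collapse = ";")
  }, character(1))
  snps <- cbind(vt$sites[, c("chrom", "pos", "ref", "alt")],
                data.frame(freq_alpine = fa, freq_foothill = ff, afd = afd,
                           outlier = out$flags, gene = gene_of,
                           region_class = class_of, stringsAsFactors = FALSE))
  structure(list(snps = snps, genes = dens, threshold = out$threshold,
                 assignments = asn),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf(
    "<scan_result> %d SNPs, %d outliers (AFD >= %.3f), %d/%d candidate genes\n",
    nrow(x$snps), sum(x$snps$outlier), x$threshold,
    sum(x$genes$candidate), nrow(x$genes)))
  invisible(x)
}

#' Write outlier SNPs as BED
#'
#' @param scan A `scan_result`.
#' @param path Output path (BED: 0-based half-open intervals).
#' @return `path`, invisibly.
#' @export
write_outlier_bed <- function(scan, path) {
  o <- scan$snps[scan$snps$outlier, ]
  writeLines(sprintf("%s\t%d\t%d\t%s\t%g", o$chrom, o$pos - 1L, o$pos,
                     ifelse(o$gene == "", ".", o$gene), o$afd), path)
  invisible(path)
}
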