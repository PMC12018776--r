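## Parallel differential expression: ecotype contrast on filtered, normalized
## negative-binomial counts with growth condition as covariate (edgeR
## glmFit/glmLRT workflow).

#' Filter genes by total read count
#'
#' Keeps genes whose count summed across all samples is strictly greater than
#' `min_total` (default 1000).
#'
#' @param counts Integer matrix, genes x samples.
#' @param min_total Total-count threshold (strict >).
#' @return The filtered matrix; attribute `n_removed` records the filter.
#' @export
filter_counts <- function(counts, min_total = 1000) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  keep <- rowSums(counts) > min_total
  if (!any(keep)) stop("no gene passes the total-count filter")
  message(sprintf("count filter: kept %d of %d genes (total > %d)",
                  sum(keep), nrow(counts), min_total))
  out <- counts[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' TMM library scaling factors
#'
#' Trimmed-mean-of-M-values normalization factors (log-ratio trim 30%,
#' abundance trim 5%), normalized so their geometric mean is 1. Larger factors
#' mean the sample's counts are scaled down more.
#'
#' @param counts Integer matrix, genes x samples (>= 2 samples).
#' @return Named numeric vector of scaling factors.
#' @export
normalize_libraries <- function(counts) {
  if (ncol(counts) < 2) stop("need >= 2 samples")
  if (any(colSums(counts) == 0)) stop("all-zero sample")
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  stats::setNames(f, colnames(counts))
}

#' Per-gene negative-binomial dispersion estimates
#'
#' Gene-wise dispersions shrunk toward the mean-dispersion trend (Cox-Reid
#' adjusted profile likelihood with empirical-Bayes shrinkage).
#'
#' @param counts Integer matrix, genes x samples.
#' @param design Design matrix (full rank, fewer columns than samples).
#' @param prior_df Prior degrees of freedom controlling shrinkage strength
#'   toward the trend (default 20).
#' @return List: `tagwise` (per-gene dispersions), `trended`, `common`.
#' @export
estimate_dispersion <- function(counts, design, prior_df = 20) {
  if (ncol(counts) <= ncol(design))
    stop("fewer residual df than 1: need more samples than design columns")
  y <- edgeR::DGEList(counts = counts)
  y <- edgeR::calcNormFactors(y, method = "TMM")
  y <- edgeR::estimateDisp(y, design, prior.df = prior_df)
  list(tagwise = stats::setNames(y$tagwise.dispersion, rownames(counts)),
       trended = y$trended.dispersion, common = y$common.dispersion)
}

#' Ecotype differential-expression test with a condition covariate
#'
#' Full workflow: total-count filter, TMM normalization, dispersion
#' estimation, per-gene negative-binomial log-linear GLM of counts on
#' ecotype + growth condition, likelihood-ratio test of the ecotype
#' coefficient, Benjamini-Hochberg adjustment, and the FDR < `fdr` call.
#' Log2 fold-changes are alpine relative to foothill.
#'
#' @param counts Integer matrix, genes x samples.
#' @param metadata Data frame with one row per sample (same order as matrix
#'   columns or matched by `sample_id`): `sample_id`, `ecotype`, `condition`.
#' @param fdr FDR threshold for the differential-expression call
#'   (default 0.1).
#' @param min_total Total-count filter threshold (default 1000).
#' @param prior_df Dispersion shrinkage prior df (default 20).
#' @return Data frame (class `dge_result`), one row per tested gene:
#'   `gene_id`, `logFC` (log2 alpine/foothill), `logCPM`, `LR`, `p`, `fdr`,
#'   `de` (logical), `direction` (`"up"`/`"down"` in alpine).
#' @export
ecotype_test <- function(counts, metadata, fdr = 0.1, min_total = 1000,
                         prior_df = 20) {
  if (!all(c("sample_id", "ecotype", "condition") %in% names(metadata)))
    stop("metadata needs sample_id, ecotype, condition")
  metadata <- metadata[match(colnames(counts), metadata$sample_id), ]
  if (any(is.na(metadata$sample_id)))
    stop("metadata does not cover every sample")
  eco <- factor(metadata$ecotype, levels = c("foothill", "alpine"))
  cond <- factor(metadata$condition)
  if (any(table(eco, cond) == 0))
    warning("some ecotype x condition cell is empty; the covariate ",
            "adjustment is not identified in that cell")
  filtered <- filter_counts(counts, min_total)
  design <- stats::model.matrix(~ eco + cond)
  y <- edgeR::DGEList(counts = filtered)
  y <- edgeR::calcNormFactors(y, method = "TMM")
  y <- edgeR::estimateDisp(y, design, prior.df = prior_df)
  fit <- edgeR::glmFit(y, design)
  lrt <- edgeR::glmLRT(fit, coef = "ecoalpine")
  tab <- lrt$table
  out <- data.frame(gene_id = rownames(tab), logFC = tab$logFC,
                    logCPM = tab$logCPM, LR = tab$LR, p = tab$PValue,
                    stringsAsFactors = FALSE)
  out$fdr <- benjamini_hochberg(out$p)
  out$de <- out$fdr < fdr
  out$direction <- ifelse(out$logFC > 0, "up", "down")
  rownames(out) <- NULL
  class(out) <- c("dge_result", "data.frame")
  out
}
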