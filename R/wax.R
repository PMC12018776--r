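## Cuticular wax GC-MS: retention indices, internal-standard/leaf-area
## normalization, per-compound ecotype tests.

#' Linear (van den Dool-Kratz) retention index
#'
#' Expresses a retention time on the scale anchored at 100 x carbon number of
#' co-injected n-alkanes: RI = 100 (n + (rt - rt_n) / (rt_(n+1) - rt_n)) with
#' the bracketing ladder rungs n and n+1 (rungs need not be consecutive
#' carbons; interpolation is linear between the bracketing rungs). Retention
#' times beyond the ladder span are extrapolated from the terminal segment and
#' flagged.
#'
#' @param rt Numeric vector of retention times (minutes).
#' @param ladder Data frame with columns `carbon` and `rt_min`, retention time
#'   strictly increasing with carbon number, >= 2 rungs.
#' @return Numeric vector of retention indices, with attribute
#'   `extrapolated` (logical vector).
#' @export
linear_retention_index <- function(rt, ladder) {
  if (nrow(ladder) < 2) stop("alkane ladder needs >= 2 rungs")
  o <- order(ladder$carbon)
  cn <- ladder$carbon[o]
  lt <- ladder$rt_min[o]
  if (any(diff(lt) <= 0))
    stop("ladder retention times must increase strictly with carbon number")
  seg <- findInterval(rt, lt, all.inside = TRUE)
  ri <- 100 * (cn[seg] + (cn[seg + 1] - cn[seg]) *
                 (rt - lt[seg]) / (lt[seg + 1] - lt[seg]))
  extrap <- rt < lt[1] | rt > lt[length(lt)]
  if (any(extrap))
    warning(sprintf("%d retention time(s) outside the ladder span: %s",
                    sum(extrap), "linearly extrapolated"))
  attr(ri, "extrapolated") <- extrap
  ri
}

#' Normalize GC-MS peak areas to per-leaf-area abundances
#'
#' Converts raw peak areas to internal-standard equivalents per leaf area:
#' `abundance = (peak_area / is_area) * is_amount_nmol / leaf_area_cm2`
#' (nmol-equivalents cm^-2). The ratio cancels per-sample detector gain, so
#' the result is invariant to jointly rescaling all areas of a sample. Peaks
#' below `min_area` are set missing (not zero), since abundances are
#' ln-transformed downstream.
#'
#' @param peaks Long-format peak table as from [simulate_peak_table()]: one
#'   row per sample x compound with `peak_area`, `is_area`, `is_amount_nmol`,
#'   `leaf_area_cm2`.
#' @param min_area Minimum detection area; smaller peaks become `NA`.
#' @return The peak table with an added `abundance_nmol_cm2` column.
#' @export
normalize_peaks <- function(peaks, min_area = 0) {
  need <- c("sample_id", "compound", "peak_area", "is_area", "is_amount_nmol",
            "leaf_area_cm2")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(is.na(peaks$is_area) | peaks$is_area <= 0))
    stop("missing or non-positive internal-standard area for some sample(s)")
  if (any(peaks$leaf_area_cm2 <= 0)) stop("leaf area must be positive")
  ab <- peaks$peak_area / peaks$is_area * peaks$is_amount_nmol /
    peaks$leaf_area_cm2
  ab[peaks$peak_area < min_area] <- NA_real_
  peaks$abundance_nmol_cm2 <- ab
  peaks
}

#' Per-compound ecotype differentiation tests
#'
#' For each compound, fits the random-intercept mixed model of ln abundance on
#' ecotype, mountain range and their interaction (no garden term: waxes are
#' sampled in one garden) with population as random intercept, extracts the
#' Type III ecotype F test, and adjusts the ecotype p values across compounds
#' by Benjamini-Hochberg. Compounds constant across samples (or with too few
#' observations) are skipped with a message.
#'
#' @param normalized Output of [normalize_peaks()] including metadata columns
#'   `population`, `ecotype`, `region`.
#' @param alpha Adjusted-p threshold for the `flagged` column (default 0.05).
#' @return Data frame, one row per tested compound: `compound`, `class`,
#'   `F_ecotype`, `dendf`, `p_ecotype`, `p_adj`, `flagged`,
#'   `log_ratio_alpine` (mean ln-abundance difference, alpine - foothill).
#' @export
compound_tests <- function(normalized, alpha = 0.05) {
  if (length(unique(normalized$ecotype)) < 2)
    stop("both ecotypes must be represented")
  res <- list()
  for (cmp in unique(normalized$compound)) {
    d <- normalized[normalized$compound == cmp &
                      !is.na(normalized$abundance_nmol_cm2), ]
    if (nrow(d) < 8 || stats::sd(d$abundance_nmol_cm2) == 0 ||
        length(unique(d$ecotype)) < 2) {
      message("skipping compound with constant or insufficient data: ", cmp)
      next
    }
    fit <- fit_trait_lmm(d, "abundance_nmol_cm2", transform = "ln",
                         drop_garden = TRUE)
    a <- anova_type3(fit)
    eco <- a[a$term == "ecotype", ]
    lr <- mean(log(d$abundance_nmol_cm2[d$ecotype == "alpine"])) -
      mean(log(d$abundance_nmol_cm2[d$ecotype == "foothill"]))
    res[[cmp]] <- data.frame(compound = cmp,
                             class = if ("class" %in% names(d)) d$class[1]
                             else NA_character_,
                             F_ecotype = eco$F, dendf = eco$dendf,
                             p_ecotype = eco$p, log_ratio_alpine = lr,
                             stringsAsFactors = FALSE)
  }
  if (!length(res)) stop("no testable compounds")
  out <- do.call(rbind, res)
  out$p_adj <- benjamini_hochberg(out$p_ecotype)
  out$flagged <- out$p_adj < alpha
  rownames(out) <- NULL
  out[, c("compound", "class", "F_ecotype", "dendf", "p_ecotype", "p_adj",
          "flagged", "log_ratio_alpine")]
}
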