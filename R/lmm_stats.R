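## Random-intercept linear mixed models for trait differentiation: REML fits,
## Type III F tests with Satterthwaite degrees of freedom, diagnostics,
## multiple-testing correction.

#' Transform a trait to its analysis scale
#'
#' Minimum conductance and wax abundances are natural-log transformed; water
#' saturation deficit and contact angles are square-root transformed.
#'
#' @param values Numeric vector.
#' @param kind One of `"ln"`, `"sqrt"`, `"none"`.
#' @return Transformed vector.
#' @export
transform_trait <- function(values, kind = c("ln", "sqrt", "none")) {
  kind <- match.arg(kind)
  bad <- switch(kind,
                ln = which(!is.na(values) & values <= 0),
                sqrt = which(!is.na(values) & values < 0),
                none = integer(0))
  if (length(bad))
    stop(sprintf("transform '%s' undefined for %d value(s) (rows %s)",
                 kind, length(bad),
                 paste(utils::head(bad, 5), collapse = ", ")))
  switch(kind, ln = log(values), sqrt = sqrt(values), none = values)
}

#' Fit the trait random-intercept mixed model
#'
#' Fits, by REML, a linear mixed model of a (transformed) trait on ecotype,
#' common garden, mountain range and the ecotype:garden and ecotype:region
#' interactions as fixed effects, with source population as a random
#' intercept:
#' `y ~ ecotype * garden + ecotype * region - ecotype:garden:region + (1 | population)`
#' (the garden terms are dropped for wax compounds, which were sampled in one
#' garden only). All factors use sum-to-zero contrasts so that Type III tests
#' are meaningful in the presence of interactions.
#'
#' @param data Data frame with the response column plus `ecotype`, `garden`
#'   (unless `drop_garden`), `region`, `population`.
#' @param response Name of the response column.
#' @param transform `"ln"`, `"sqrt"` or `"none"` (applied before fitting).
#' @param drop_garden Logical; omit the garden main effect and interaction.
#' @param extra_fixed Optional character vector of additional fixed-effect
#'   terms.
#' @return Object of class `lmm_fit`: list with the fitted `lmerTest` model
#'   (`model`), `response`, `transform`, `n_used`, `n_dropped` (listwise
#'   deletions), variance components `sigma2_pop` and `sigma2_resid`, and the
#'   REML criterion value `reml`.
#' @export
fit_trait_lmm <- function(data, response, transform = "none",
                          drop_garden = FALSE, extra_fixed = NULL) {
  need <- c(response, "ecotype", "region", "population",
            if (!drop_garden) "garden")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[, need]), need, drop = FALSE]
  n_dropped <- nrow(data) - nrow(d)
  if (n_dropped > 0)
    message(sprintf("dropped %d row(s) with missing values for %s",
                    n_dropped, response))
  if (length(unique(d$population)) < 2)
    stop("need >= 2 populations to fit a population random intercept")
  d$.y <- transform_trait(d[[response]], transform)
  for (f in c("ecotype", "garden", "region", "population")) {
    if (f %in% names(d)) {
      d[[f]] <- factor(d[[f]])
      if (f != "population" && nlevels(d[[f]]) > 1)
        stats::contrasts(d[[f]]) <- stats::contr.sum(nlevels(d[[f]]))
    }
  }
  terms <- if (drop_garden) c("ecotype", "region", "ecotype:region")
  else c("ecotype", "garden", "region", "ecotype:garden", "ecotype:region")
  terms <- c(terms, extra_fixed)
  fml <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + "),
                                 "+ (1 | population)"))
  fit <- lmerTest::lmer(fml, data = d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2p <- vc$vcov[vc$grp == "population"]
  s2e <- vc$vcov[vc$grp == "Residual"]
  structure(list(model = fit, response = response, transform = transform,
                 data = d, n_used = nrow(d), n_dropped = n_dropped,
                 sigma2_pop = s2p, sigma2_resid = s2e,
                 reml = as.numeric(stats::deviance(fit, REML = TRUE))),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf(
    "<lmm_fit> %s (%s scale): n = %d, sigma2_pop = %.4g, sigma2_resid = %.4g\n",
    x$response, x$transform, x$n_used, x$sigma2_pop, x$sigma2_resid))
  invisible(x)
}

#' Type III analysis-of-variance table with Satterthwaite df
#'
#' Per fixed-effect term, the Wald F statistic for the Type III contrast under
#' sum-to-zero coding, with fractional denominator degrees of freedom by
#' Satterthwaite's approximation (the variance of the estimated contrast
#' variance propagated through the REML variance-component covariance).
#'
#' @param fit An [fit_trait_lmm()] object.
#' @return Data frame: `term`, `sumsq`, `numdf`, `dendf`, `F`, `p`.
#' @export
anova_type3 <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  a <- stats::anova(fit$model, type = 3, ddf = "Satterthwaite")
  out <- data.frame(term = rownames(a), sumsq = a[["Sum Sq"]],
                    numdf = a[["NumDF"]], dendf = a[["DenDF"]],
                    F = a[["F value"]], p = a[["Pr(>F)"]],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment controlling the FDR across a family of tests. Adjusted
#' values are monotone in rank, never below the raw p, and capped at 1.
#'
#' @param pvalues Numeric vector of raw p values in \[0, 1\] (NA passed
#'   through).
#' @return Adjusted p values.
#' @export
benjamini_hochberg <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p values must be in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Mixed-model diagnostics: Levene's test and variance inflation factors
#'
#' Homogeneity of the conditional-residual variance across populations is
#' tested with the Brown-Forsythe (median-centred) Levene test; collinearity
#' of the fixed design is summarised by per-column variance inflation factors
#' from the correlation matrix of the non-intercept model-matrix columns
#' (infinite VIF flags an aliased column).
#'
#' @param fit An [fit_trait_lmm()] object.
#' @param group_by Grouping for Levene's test (column of the model data;
#'   default `"population"`).
#' @return List with `levene` (list: `statistic`, `df`, `p`) and `vif`
#'   (named numeric vector).
#' @export
lmm_diagnostics <- function(fit, group_by = "population") {
  stopifnot(inherits(fit, "lmm_fit"))
  res <- stats::residuals(fit$model)
  grp <- factor(fit$data[[group_by]])
  if (nlevels(grp) < 2) stop("Levene's test needs >= 2 groups")
  ## Brown-Forsythe: one-way ANOVA on |residual - group median|
  z <- abs(res - stats::ave(res, grp, FUN = stats::median))
  an <- stats::anova(stats::lm(z ~ grp))
  levene <- list(statistic = an[["F value"]][1],
                 df = c(an[["Df"]][1], an[["Df"]][2]),
                 p = an[["Pr(>F)"]][1])
  X <- lme4::getME(fit$model, "X")
  keep <- colnames(X) != "(Intercept)"
  Xc <- X[, keep, drop = FALSE]
  nz <- apply(Xc, 2, stats::sd) > 0
  vif <- rep(Inf, ncol(Xc))
  names(vif) <- colnames(Xc)
  if (any(nz)) {
    R <- stats::cor(Xc[, nz, drop = FALSE])
    vif[nz] <- tryCatch(diag(solve(R)), error = function(e)
      rep(Inf, sum(nz)))
  }
  list(levene = levene, vif = vif)
}

#' Fit and test all four cuticle traits
#'
#' Convenience wrapper running [fit_trait_lmm()] and [anova_type3()] for
#' minimum conductance (ln), water saturation deficit (sqrt) and both contact
#' angles (sqrt) on a trait table.
#'
#' @param traits Trait table as produced by [compute_traits()] or
#'   [simulate_traits()].
#' @return Named list of lists, each with `fit` and `anova`.
#' @export
trait_anova_tables <- function(traits) {
  specs <- list(gmin_m_s = "ln", wsd_pct = "sqrt",
                theta_adaxial = "sqrt", theta_abaxial = "sqrt")
  out <- list()
  for (resp in names(specs)) {
    fit <- fit_trait_lmm(traits, resp, transform = specs[[resp]])
    out[[resp]] <- list(fit = fit, anova = anova_type3(fit))
  }
  out
}
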