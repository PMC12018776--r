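# Independent oracles used across tests.

# Brute-force profiled REML surface for y = X beta + Z b + e with a single
# random intercept: lambda = sigma2_pop / sigma2_resid, V = I + lambda ZZ'.
# Returns the profiled REML "deviance" (up to an additive constant w.r.t. the
# lme4 convention), the profiled residual variance and beta at a given lambda.
reml_profile <- function(lambda, y, X, Z) {
  n <- nrow(X)
  p <- ncol(X)
  V <- diag(n) + lambda * tcrossprod(Z)
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  beta <- solve(XtVi %*% X, XtVi %*% y)
  r <- y - X %*% beta
  s2 <- c(t(r) %*% Vi %*% r) / (n - p)
  dev <- c(determinant(V)$modulus) + c(determinant(XtVi %*% X)$modulus) +
    (n - p) * (1 + log(2 * pi * s2))
  list(dev = dev, s2_resid = s2, s2_pop = lambda * s2, beta = c(beta))
}

# Grid search + golden-section refinement of the REML surface over lambda.
reml_grid_search <- function(y, X, Z, upper = 50) {
  grid <- seq(0, upper, length.out = 201)
  devs <- vapply(grid, function(l) reml_profile(l, y, X, Z)$dev, numeric(1))
  i <- which.min(devs)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(function(l) reml_profile(l, y, X, Z)$dev,
                         c(lo, hi), tol = 1e-12)
  c(reml_profile(opt$minimum, y, X, Z), lambda = opt$minimum)
}

# Manual Benjamini-Hochberg step-up, written independently of p.adjust.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Minimal hand-built variant table.
toy_variants <- function(dosages, ecotypes, chrom = "chr1",
                         pos = seq_len(nrow(dosages)), ploidy = 4) {
  n_ind <- ncol(dosages)
  colnames(dosages) <- sprintf("ind%02d", seq_len(n_ind))
  structure(list(
    sites = data.frame(chrom = chrom, pos = pos,
                       ref = rep("A", nrow(dosages)),
                       alt = rep("T", nrow(dosages)),
                       stringsAsFactors = FALSE),
    dosage = dosages,
    individuals = data.frame(indiv_id = colnames(dosages),
                             population = paste0("pop", seq_len(n_ind)),
                             ecotype = ecotypes,
                             region = "R1", stringsAsFactors = FALSE),
    ploidy = as.integer(ploidy)), class = "variant_table")
}

# Hand-built gene_models object.
toy_genes <- function(genes, cds) {
  structure(list(genes = genes, cds = cds), class = "gene_models")
}
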