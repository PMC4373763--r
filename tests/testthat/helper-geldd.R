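# Shared fixtures and independent oracles. Everything here is built in code
# at test time; no stored data.

# Quick spot table from a volume matrix (rows = spots).
make_table <- function(volumes, x = NULL, y = NULL, normalized = FALSE,
                       gradient = "4-7") {
  n <- nrow(volumes)
  if (is.null(x)) x <- seq(0.05, 0.95, length.out = n)
  if (is.null(y)) y <- rev(seq(0.05, 0.95, length.out = n))
  spot_table(sprintf("spot_%04d", seq_len(n)), x, y, gradient, volumes,
             normalized = normalized)
}

# A variability profile whose predicted threshold is a given constant,
# obtained through the real fitting path (intercept-only on constant q95).
constant_profile <- function(table, threshold) {
  stopifnot(threshold >= 1)
  spots <- data.frame(spot_id = table$spot_id,
                      q95 = threshold,
                      log_mean_volume = log(rowMeans(
                        table$volumes[, grep("^control_",
                                             colnames(table$volumes)),
                                      drop = FALSE])),
                      x = table$x, y = table$y,
                      stringsAsFactors = FALSE)
  fit_threshold_glm(spots, intercept_only = TRUE)
}

# Exact distribution oracle for the bootstrap fold quantile: enumerate all
# equally likely ordered resamples of the two pseudo-groups and take the
# type-7 quantile of the resulting fold values.
enum_fold_quantile <- function(v, sizes, q) {
  k <- length(v)
  tuple_means <- function(size) {
    g <- as.matrix(expand.grid(rep(list(seq_len(k)), size)))
    rowMeans(matrix(v[g], nrow(g)))
  }
  m1 <- tuple_means(sizes[1L])
  m2 <- tuple_means(sizes[2L])
  f <- outer(m1, m2, function(a, b) pmax(a, b) / pmin(a, b))
  unname(stats::quantile(as.vector(f), q, type = 7))
}

# Brute-force BH definition: adj_(i) = min_{j >= i} min(1, m p_(j) / j).
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m), function(i) {
    min(1, min(ps[i:m] * m / (i:m)))
  }, numeric(1L))
  adj[order(o)]
}

# Independent vectorized Monte-Carlo Welch power (its own formulas, no call
# into the package).
mc_welch_power <- function(sd, n, fold, alpha = 0.05, nsim = 1e5) {
  a <- matrix(stats::rnorm(n * nsim, 0, sd), n)
  b <- matrix(stats::rnorm(n * nsim, log(fold), sd), n)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- (colSums(a^2) - n * ma^2) / (n - 1)
  vb <- (colSums(b^2) - n * mb^2) / (n - 1)
  se2 <- va / n + vb / n
  tt <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / n)^2 / (n - 1) + (vb / n)^2 / (n - 1))
  mean(2 * stats::pt(-abs(tt), df) <= alpha)
}

# Small two-group volume matrix with exact per-group values.
two_group_matrix <- function(control, knockdown, wildtype = NULL) {
  stopifnot(is.matrix(control), is.matrix(knockdown))
  colnames(control) <- paste0("control_", seq_len(ncol(control)))
  colnames(knockdown) <- paste0("knockdown_", seq_len(ncol(knockdown)))
  out <- cbind(control, knockdown)
  if (!is.null(wildtype)) {
    colnames(wildtype) <- paste0("wildtype_", seq_len(ncol(wildtype)))
    out <- cbind(out, wildtype)
  }
  out
}

# Hit list shorthand.
mk_hits <- function(spot_id, condition, accession, length, spectra,
                    scores = NULL) {
  if (is.null(scores)) {
    scores <- lapply(spectra, function(k) rep(50, max(k, 3L)))
  }
  hit_list(spot_id, condition, accession, length, spectra,
           ion_scores = scores)
}
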