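# Power analysis for pilot sample-size planning: per-spot detection power
# of the two-sample comparison on log volumes, and the fraction-of-spots
# power profile over a grid of sample sizes.

# Exact power of the two-sided Welch test for two equal-size normal samples
# with a common SD, by quadrature. Conditional on the two sample variances,
# the numerator of the Welch statistic is normal, the scaled variance total
# S ~ chi^2_{2(n-1)}, and the variance split B ~ Beta((n-1)/2, (n-1)/2)
# determines the Satterthwaite df. Integrating the conditional rejection
# probability over (S, B) with Gauss-Legendre nodes gives the exact power
# to ~1e-4, without simulation. Vectorized over `ncp`.
welch_power_ncp <- function(ncp, n, alpha, nodes = 48L) {
  m <- n - 1
  g <- gauss_legendre_01(nodes)
  B <- stats::qbeta(g$x, m / 2, m / 2)
  S <- stats::qchisq(g$x, 2 * m)
  dfh <- m / (B^2 + (1 - B)^2)
  tc <- stats::qt(1 - alpha / 2, dfh)
  crit <- outer(sqrt(S / (2 * m)), tc)      # nodes_S x nodes_B
  w <- outer(g$w, g$w)
  pow <- numeric(length(ncp))
  for (i in seq_along(crit)) {
    pow <- pow + w[i] * (1 - stats::pnorm(crit[i] - ncp) +
                           stats::pnorm(-crit[i] - ncp))
  }
  pow
}

#' Detection power for one spot
#'
#' Power of the two-sided two-sample test on log volumes to detect a true
#' fold change `fold` for a spot whose log-volume standard deviation is
#' `log_sd`, with `n_per_group` replicates per group at level `alpha`. The
#' standardized effect is `log(fold) / log_sd` and the noncentrality
#' parameter `log(fold)/log_sd * sqrt(n/2)`.
#'
#' Two methods are offered: `"welch"` (default) computes the exact power of
#' the Welch test by quadrature over the variance-estimate distribution —
#' consistent with the test the pipeline actually runs — while `"pooled"`
#' is the classical noncentral-t power of the equal-variance test with
#' `2n - 2` degrees of freedom (the textbook sample-size formula; slightly
#' optimistic for small n).
#'
#' @param log_sd strictly positive log-scale SD (vectorized).
#' @param n_per_group replicates per group (>= 2).
#' @param fold true fold change (> 0; `fold` and `1/fold` give the same
#'   power).
#' @param alpha two-sided significance level.
#' @param method `"welch"` or `"pooled"`.
#' @return power in `[0, 1]`, same length as `log_sd`.
#' @export
spot_power <- function(log_sd, n_per_group, fold, alpha = 0.05,
                       method = c("welch", "pooled")) {
  method <- match.arg(method)
  n <- check_count(n_per_group, "n_per_group", min = 2L)
  if (any(!is.finite(log_sd) | log_sd <= 0)) {
    stop("'log_sd' must be strictly positive", call. = FALSE)
  }
  check_positive_scalar(fold, "fold")
  stopifnot(alpha > 0, alpha < 1)
  ncp <- abs(log(fold)) / log_sd * sqrt(n / 2)
  if (method == "pooled") {
    df <- 2 * n - 2
    tc <- stats::qt(1 - alpha / 2, df)
    1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
  } else {
    welch_power_ncp(ncp, n, alpha)
  }
}

#' Power settings for sample-size planning
#'
#' @param alpha two-sided significance level (default 0.05).
#' @param target_power per-spot power considered sufficient (default 0.8).
#' @param folds fold changes of interest (default `c(2, 1.5)`).
#' @param n_grid candidate per-group sample sizes (default `2:12`).
#' @return an object of class `power_settings`.
#' @export
power_settings <- function(alpha = 0.05, target_power = 0.8,
                           folds = c(2, 1.5), n_grid = 2:12) {
  stopifnot(alpha > 0, alpha < 1, target_power > 0, target_power < 1,
            all(folds > 1), length(n_grid) >= 1L, all(n_grid >= 2))
  structure(list(alpha = alpha, target_power = target_power,
                 folds = as.numeric(folds),
                 n_grid = sort(unique(as.integer(n_grid)))),
            class = "power_settings")
}

#' Fraction-of-spots power profile over sample sizes
#'
#' The pilot-design question: given the distribution of per-spot log-scale
#' SDs observed in a pilot experiment, what fraction of spots reaches the
#' target power at each candidate sample size and fold change, and what is
#' the smallest sample size meeting a coverage goal?
#'
#' @param per_spot_log_sd positive per-spot log-scale SDs.
#' @param settings a [power_settings()].
#' @param coverage_goal optional fraction of spots that must reach the
#'   target power; when given, a recommended n per fold is reported
#'   (`NA` if no n in the grid suffices).
#' @param method power method, see [spot_power()].
#' @return a `power_profile`: list with `table` (data frame `n`, `fold`,
#'   `fraction`), `recommended` (named by fold, or `NULL`), `settings`.
#' @export
sample_size_profile <- function(per_spot_log_sd,
                                settings = power_settings(),
                                coverage_goal = NULL,
                                method = c("welch", "pooled")) {
  method <- match.arg(method)
  sds <- as.numeric(per_spot_log_sd)
  if (!length(sds)) stop("empty per-spot SD list", call. = FALSE)
  if (any(!is.finite(sds) | sds <= 0)) {
    stop("per-spot SDs must be strictly positive", call. = FALSE)
  }
  stopifnot(inherits(settings, "power_settings"))
  grid <- expand.grid(n = settings$n_grid, fold = settings$folds,
                      KEEP.OUT.ATTRS = FALSE)
  grid$fraction <- mapply(function(n, fold) {
    mean(spot_power(sds, n, fold, settings$alpha, method = method) >=
           settings$target_power)
  }, grid$n, grid$fold)
  recommended <- NULL
  if (!is.null(coverage_goal)) {
    stopifnot(coverage_goal > 0, coverage_goal <= 1)
    recommended <- vapply(settings$folds, function(f) {
      sub <- grid[grid$fold == f, ]
      hit <- sub$n[sub$fraction >= coverage_goal]
      if (length(hit)) min(hit) else NA_integer_
    }, numeric(1L))
    names(recommended) <- as.character(settings$folds)
  }
  structure(list(table = grid, recommended = recommended,
                 settings = settings, method = method),
            class = "power_profile")
}

#' @export
print.power_profile <- function(x, ...) {
  cat("power_profile (fraction of spots reaching target power)\n")
  wide <- stats::reshape(x$table, idvar = "n", timevar = "fold",
                         direction = "wide")
  print(wide, row.names = FALSE)
  if (!is.null(x$recommended)) {
    cat("recommended n per fold:\n")
    print(x$recommended)
  }
  invisible(x)
}

#' Calibrate a per-spot SD distribution to a pilot-design statement
#'
#' Rescales a base SD distribution by bisection so that exactly a target
#' fraction of spots reaches the target power at a given (n, fold) — the
#' standard way to construct a synthetic pilot whose power profile matches
#' a stated design outcome ("n replicates give power 0.8 at fold 2 for
#' 96% of spots"). The returned scale is the largest value for which the
#' boundary spot still reaches the target, so the achieved coverage equals
#' `ceiling(coverage * length(base_sds)) / length(base_sds)` exactly.
#'
#' @param base_sds positive SDs defining the distribution's shape.
#' @param coverage target fraction of spots at or above the target power.
#' @param n_per_group,fold,alpha,target_power design point, see
#'   [spot_power()].
#' @param method power method.
#' @param tol bisection tolerance on the scale factor.
#' @return the positive scale factor to multiply `base_sds` by.
#' @export
calibrate_sd_scale <- function(base_sds, coverage = 0.96, n_per_group = 7L,
                               fold = 2, alpha = 0.05, target_power = 0.8,
                               method = c("welch", "pooled"), tol = 1e-12) {
  method <- match.arg(method)
  sds <- sort(as.numeric(base_sds))
  stopifnot(length(sds) >= 2L, all(sds > 0), coverage > 0, coverage <= 1)
  k <- ceiling(coverage * length(sds))
  sd_k <- sds[k]  # boundary spot: the k-th smallest SD must reach target
  pow <- function(scale) spot_power(scale * sd_k, n_per_group, fold, alpha,
                                    method = method)
  lo <- 1e-6; hi <- 1
  while (pow(hi) >= target_power) { lo <- hi; hi <- hi * 2 }
  if (pow(lo) < target_power) {
    stop("base SDs too large to reach the target power at any scale <= 1e-6",
         call. = FALSE)
  }
  # invariant: pow(lo) >= target > pow(hi); return lo (feasible side)
  while (hi - lo > tol * hi) {
    mid <- (lo + hi) / 2
    if (pow(mid) >= target_power) lo <- mid else hi <- mid
  }
  lo
}
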