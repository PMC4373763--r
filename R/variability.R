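# Intrinsic spot variability: bootstrap null fold-change quantiles from
# control replicates and a GLM that smooths them over log mean volume and
# gel position to give every spot a predicted significance threshold.

#' Bootstrap settings
#'
#' @param n_boot number of bootstrap repetitions per spot (default 1000).
#' @param subgroup_sizes sizes of the two pseudo-groups resampled with
#'   replacement from the control replicates (default `c(7, 7)`, matching a
#'   7 vs 7 design; the unbalanced `c(6, 7)` variant is available here).
#' @param quantile which quantile of the null fold distribution to report
#'   (default 0.95).
#' @param seed master integer seed.
#' @return an object of class `bootstrap_settings`.
#' @export
bootstrap_settings <- function(n_boot = 1000L, subgroup_sizes = c(7L, 7L),
                               quantile = 0.95, seed = 1L) {
  n_boot <- check_count(n_boot, "n_boot", min = 1L)
  stopifnot(length(subgroup_sizes) == 2L)
  if (any(subgroup_sizes < 2)) {
    stop("subgroup sizes must be >= 2", call. = FALSE)
  }
  if (!(quantile > 0 && quantile < 1)) {
    stop("'quantile' must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(list(n_boot = n_boot,
                 subgroup_sizes = as.integer(subgroup_sizes),
                 quantile = quantile, seed = as.integer(seed)),
            class = "bootstrap_settings")
}

#' Bootstrap quantile of a spot's intrinsic fold-change distribution
#'
#' Resamples two pseudo-groups with replacement from one spot's control
#' replicates, forms the orientation-free fold difference of their means,
#' `max(m1, m2) / min(m1, m2)`, repeats `n_boot` times, and returns the
#' configured empirical quantile (type-7 linear interpolation). The result
#' is the fold change that spot produces by chance alone at the configured
#' probability level — the noise floor a real effect must exceed.
#'
#' The fold is scale-free (invariant to rescaling all volumes) and
#' symmetric in the two pseudo-groups, so the returned quantile is always
#' `>= 1`.
#'
#' @param control_volumes numeric vector of strictly positive control
#'   volumes for one spot (>= 2 values).
#' @param settings a [bootstrap_settings()]; the seed used is
#'   `settings$seed` mixed with `substream` so per-spot substreams are
#'   independent and reproducible.
#' @param substream integer substream counter (e.g. the spot index).
#' @return the bootstrap fold quantile, a scalar `>= 1`.
#' @export
bootstrap_fold_quantile <- function(control_volumes,
                                    settings = bootstrap_settings(),
                                    substream = 0L) {
  v <- as.numeric(control_volumes)
  if (length(v) < 2L) {
    stop("need at least 2 control replicates", call. = FALSE)
  }
  if (any(!is.finite(v) | v <= 0)) {
    stop("control volumes must be strictly positive", call. = FALSE)
  }
  n1 <- settings$subgroup_sizes[1L]
  n2 <- settings$subgroup_sizes[2L]
  B <- settings$n_boot
  set.seed(substream_seed(settings$seed, substream))
  idx <- sample.int(length(v), (n1 + n2) * B, replace = TRUE)
  m <- matrix(v[idx], nrow = n1 + n2, ncol = B)
  m1 <- colMeans(m[seq_len(n1), , drop = FALSE])
  m2 <- colMeans(m[n1 + seq_len(n2), , drop = FALSE])
  folds <- pmax(m1, m2) / pmin(m1, m2)
  unname(stats::quantile(folds, settings$quantile, type = 7))
}

#' Per-spot intrinsic variability of a whole table
#'
#' Applies [bootstrap_fold_quantile()] to every spot's control replicates.
#' Spots with any non-positive control volume are excluded with a warning
#' (fold changes on zero means are undefined).
#'
#' @param table a [spot_table()] (normalized recommended).
#' @param settings a [bootstrap_settings()].
#' @return data frame: `spot_id`, `q95`, `log_mean_volume` (natural log of
#'   the control mean), `x`, `y`.
#' @export
estimate_variability <- function(table, settings = bootstrap_settings()) {
  stopifnot(inherits(table, "spot_table"))
  ctrl <- group_volumes(table, "control")
  if (!ncol(ctrl)) stop("table has no control gels", call. = FALSE)
  ok <- apply(ctrl, 1L, function(v) all(is.finite(v) & v > 0))
  if (!all(ok)) {
    warning(sprintf(
      "%d spot(s) with non-positive control volumes excluded from bootstrap: %s",
      sum(!ok), paste(utils::head(table$spot_id[!ok], 5L), collapse = ", ")),
      call. = FALSE)
  }
  keep <- which(ok)
  q <- vapply(keep, function(i) {
    bootstrap_fold_quantile(ctrl[i, ], settings, substream = i)
  }, numeric(1L))
  data.frame(spot_id = table$spot_id[keep],
             q95 = q,
             log_mean_volume = log(rowMeans(ctrl[keep, , drop = FALSE])),
             x = table$x[keep], y = table$y[keep],
             stringsAsFactors = FALSE)
}

#' Fit the threshold GLM to per-spot bootstrap quantiles
#'
#' Models the intrinsic variability surface as
#' `log(q95) ~ intercept + b1 * log(mean volume) + b2 * x + b3 * y`
#' with Gaussian error (a Gaussian GLM with log-transformed response,
#' i.e. a multiplicative mean model — natural for fold quantiles, which are
#' `>= 1` and positively skewed). The fitted surface smooths the noisy
#' per-spot quantiles into a spot-specific significance threshold,
#' `exp(fitted)`, floored at 1.
#'
#' @param spots data frame as returned by [estimate_variability()]:
#'   columns `spot_id`, `q95`, `log_mean_volume`, `x`, `y`.
#' @param intercept_only fall back to an intercept-only fit (no
#'   covariates); use when the design is degenerate.
#' @return an object of class `variability_profile`: list with `data`
#'   (the input plus `predicted_threshold`), `coefficients`, `sigma`,
#'   `residual_deviance`, `n`, and the fitted `lm` terms needed for
#'   prediction.
#' @export
fit_threshold_glm <- function(spots, intercept_only = FALSE) {
  spots <- as.data.frame(spots)
  needed <- c("spot_id", "q95", "log_mean_volume", "x", "y")
  stopifnot(all(needed %in% names(spots)))
  if (nrow(spots) < 10L) {
    stop("need at least 10 spots to fit the threshold model", call. = FALSE)
  }
  if (any(spots$q95 < 1)) stop("all q95 must be >= 1", call. = FALSE)
  form <- if (intercept_only) log(q95) ~ 1 else
    log(q95) ~ log_mean_volume + x + y
  X <- stats::model.matrix(form, spots)
  if (qr(X)$rank < ncol(X)) {
    stop(paste("rank-deficient design (constant covariate?);",
               "consider intercept_only = TRUE"), call. = FALSE)
  }
  fit <- stats::glm(form, family = stats::gaussian(), data = spots)
  co <- stats::coef(fit)
  full <- c("(Intercept)" = 0, log_mean_volume = 0, x = 0, y = 0)
  full[names(co)] <- co
  data <- spots
  data$predicted_threshold <- pmax(1, exp(stats::fitted(fit)))
  structure(
    list(data = data,
         coefficients = full,
         intercept_only = intercept_only,
         sigma = sqrt(summary(fit)$dispersion),
         residual_deviance = stats::deviance(fit),
         n = nrow(spots)),
    class = "variability_profile")
}

#' @export
print.variability_profile <- function(x, ...) {
  cat(sprintf("variability_profile: %d spots, sigma = %.4f\n", x$n, x$sigma))
  cat("  log(q95) coefficients:\n")
  print(round(x$coefficients, 5))
  cat(sprintf("  predicted thresholds: %.3f - %.3f\n",
              min(x$data$predicted_threshold),
              max(x$data$predicted_threshold)))
  invisible(x)
}

#' Predict spot-specific thresholds from a fitted variability profile
#'
#' Evaluates the threshold surface `max(1, exp(linear predictor))` for new
#' spots. Spots with a non-positive control mean are excluded with a
#' warning (their threshold is `NA` in the returned vector).
#'
#' @param profile a `variability_profile` from [fit_threshold_glm()].
#' @param spots a [spot_table()] (control means and coordinates are taken
#'   from it) or a data frame with columns `log_mean_volume`, `x`, `y`.
#' @return named numeric vector of thresholds `>= 1`, aligned to spot order.
#' @export
predict_thresholds <- function(profile, spots) {
  stopifnot(inherits(profile, "variability_profile"))
  if (inherits(spots, "spot_table")) {
    ctrl <- group_volumes(spots, "control")
    means <- rowMeans(ctrl)
    newdata <- data.frame(spot_id = spots$spot_id,
                          log_mean_volume = ifelse(means > 0, log(means),
                                                   NA_real_),
                          x = spots$x, y = spots$y,
                          stringsAsFactors = FALSE)
  } else {
    newdata <- as.data.frame(spots)
    if (is.null(newdata$spot_id)) {
      newdata$spot_id <- as.character(seq_len(nrow(newdata)))
    }
  }
  bad <- !is.finite(newdata$log_mean_volume)
  if (any(bad)) {
    warning(sprintf("%d spot(s) with non-positive control mean excluded: %s",
                    sum(bad),
                    paste(utils::head(newdata$spot_id[bad], 5L),
                          collapse = ", ")), call. = FALSE)
  }
  co <- profile$coefficients
  lp <- co[["(Intercept)"]] +
    co[["log_mean_volume"]] * newdata$log_mean_volume +
    co[["x"]] * newdata$x + co[["y"]] * newdata$y
  thr <- pmax(1, exp(lp))
  thr[bad] <- NA_real_
  stats::setNames(thr, newdata$spot_id)
}

#' Write / read a variability profile
#'
#' The per-spot table goes to CSV (`spot_id`, `q95`, `log_mean_volume`,
#' `x`, `y`, `predicted_threshold`); the GLM coefficients and fit
#' diagnostics to a JSON sidecar `<path>.coefficients.json`.
#'
#' @param profile a `variability_profile`.
#' @param path CSV output path.
#' @param comments optional comment lines for the CSV header.
#' @return `path`, invisibly.
#' @export
write_variability_profile <- function(profile, path,
                                      comments = character()) {
  stopifnot(inherits(profile, "variability_profile"))
  con <- file(path, "w")
  writeLines(c("# geldd variability profile v1",
               if (length(comments)) paste("#", comments)), con)
  utils::write.csv(profile$data, con, row.names = FALSE, quote = FALSE)
  close(con)
  jsonlite::write_json(
    list(coefficients = as.list(profile$coefficients),
         intercept_only = profile$intercept_only,
         sigma = profile$sigma,
         residual_deviance = profile$residual_deviance,
         n = profile$n),
    paste0(path, ".coefficients.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_variability_profile
#' @export
read_variability_profile <- function(path) {
  data <- utils::read.csv(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".coefficients.json"),
                              simplifyVector = TRUE)
  structure(
    list(data = data,
         coefficients = unlist(meta$coefficients),
         intercept_only = isTRUE(meta$intercept_only),
         sigma = meta$sigma,
         residual_deviance = meta$residual_deviance,
         n = meta$n),
    class = "variability_profile")
}
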