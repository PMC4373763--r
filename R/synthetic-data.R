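# Synthetic data generator: spot-volume tables and MS hit lists with the
# statistical structure the downstream analysis assumes, so every stage of
# the pipeline can be exercised and validated without any gel data.

#' Simulation configuration for synthetic spot tables
#'
#' Describes one simulated 2DE differential-display experiment. Spot volumes
#' are drawn from a log-normal law: for spot *i* on gel *g*,
#' `log V_ig ~ Normal(mu_i + log(fold_i) * [g in knockdown], sd_i)`, where
#' `mu_i` is the spot's log mean volume (uniform over
#' `log_volume_mean_range`), `fold_i` is 1 except for spiked spots, and the
#' per-spot log-scale standard deviation (~ relative SD for small values)
#' follows a smooth trend over log mean volume and gel position:
#' `sd_i = cv_intercept * exp(cv_slope_logvolume * (mu_i - mu_c) +
#'   cv_coeff_x * (x_i - 0.5) + cv_coeff_y * (y_i - 0.5))`
#' with `mu_c` the midpoint of `log_volume_mean_range`. This mirrors the
#' mean- and position-dependent variability that the threshold GLM of the
#' analysis is designed to capture.
#'
#' Defaults describe a typical replicated 2DE experiment: 7 biological
#' replicates per cell line, around 2000 spots per gradient, volumes
#' spanning three orders of magnitude, relative SD near 30% that decreases
#' with spot volume.
#'
#' @param n_spots number of spots (>= 1).
#' @param n_replicates_per_group biological replicates per group (>= 2).
#' @param groups ordered subset of `c("control", "knockdown", "wildtype")`;
#'   must contain control and knockdown.
#' @param log_volume_mean_range range of per-spot log mean volumes
#'   (natural-log scale).
#' @param cv_intercept relative SD at the reference point (mid log-volume,
#'   gel centre); > 0.
#' @param cv_slope_logvolume change of log relative-SD per unit log mean
#'   volume (typically negative: big spots are more reproducible).
#' @param cv_coeff_x,cv_coeff_y positional trend of log relative-SD over the
#'   unit square.
#' @param spiked_spots data frame with columns `index` (1-based spot index)
#'   and `fold` (> 0, true knockdown/control fold change), or `NULL`.
#' @param gradient IPG gradient label.
#' @param dropout_rate probability that an individual volume is zeroed
#'   (missing spot); 0 by default — the analysis assumes edited,
#'   complete spot sets.
#' @param seed master integer seed.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_spots = 2000L,
                              n_replicates_per_group = 7L,
                              groups = c("control", "knockdown"),
                              log_volume_mean_range = log(c(1e4, 1e7)),
                              cv_intercept = 0.30,
                              cv_slope_logvolume = -0.05,
                              cv_coeff_x = 0.30,
                              cv_coeff_y = 0.20,
                              spiked_spots = NULL,
                              gradient = "4-7",
                              dropout_rate = 0,
                              seed = 1L) {
  n_spots <- check_count(n_spots, "n_spots", min = 1L)
  n_replicates_per_group <- check_count(n_replicates_per_group,
                                        "n_replicates_per_group", min = 2L)
  groups <- match.arg(groups, VALID_GROUPS, several.ok = TRUE)
  if (!all(c("control", "knockdown") %in% groups)) {
    stop("'groups' must contain both 'control' and 'knockdown'",
         call. = FALSE)
  }
  stopifnot(length(log_volume_mean_range) == 2L,
            diff(log_volume_mean_range) >= 0)
  check_positive_scalar(cv_intercept, "cv_intercept")
  if (!is.null(spiked_spots)) {
    spiked_spots <- as.data.frame(spiked_spots)
    if (!all(c("index", "fold") %in% names(spiked_spots))) {
      stop("'spiked_spots' needs columns 'index' and 'fold'", call. = FALSE)
    }
    if (any(spiked_spots$fold <= 0)) {
      stop("spiked folds must be > 0", call. = FALSE)
    }
    if (anyDuplicated(spiked_spots$index) ||
        any(spiked_spots$index < 1 | spiked_spots$index > n_spots)) {
      stop("spiked spot indices must be unique and in 1..n_spots",
           call. = FALSE)
    }
  }
  stopifnot(dropout_rate >= 0, dropout_rate < 1)
  structure(
    list(n_spots = n_spots,
         n_replicates_per_group = n_replicates_per_group,
         groups = groups,
         log_volume_mean_range = as.numeric(log_volume_mean_range),
         cv_intercept = cv_intercept,
         cv_slope_logvolume = cv_slope_logvolume,
         cv_coeff_x = cv_coeff_x,
         cv_coeff_y = cv_coeff_y,
         spiked_spots = spiked_spots,
         gradient = as.character(gradient),
         dropout_rate = dropout_rate,
         seed = as.integer(seed)),
    class = "simulation_config")
}

#' Generate a synthetic spot table with ground truth
#'
#' Draws a spots x gels volume matrix under the log-normal model documented
#' in [simulation_config()]. Each spot consumes its own deterministic RNG
#' substream derived from the master seed, so identical configurations
#' reproduce the identical table bit-for-bit regardless of how many spots
#' are generated before or after.
#'
#' @param config a [simulation_config()].
#' @return list with elements `table` (a [spot_table()], raw volumes) and
#'   `truth` (data frame: `spot_id`, `true_log_mean`, `true_mean_volume`,
#'   `true_fold`, `true_log_sd`).
#' @export
generate_spot_table <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_spots
  reps <- config$n_replicates_per_group
  gels <- unlist(lapply(config$groups,
                        function(g) paste(g, seq_len(reps), sep = "_")))
  fold <- rep(1, n)
  if (!is.null(config$spiked_spots)) {
    fold[config$spiked_spots$index] <- config$spiked_spots$fold
  }
  mu_c <- mean(config$log_volume_mean_range)
  kd <- grepl("^knockdown_", gels)

  x <- y <- mu <- sdl <- numeric(n)
  vols <- matrix(0, n, length(gels), dimnames = list(NULL, gels))
  for (i in seq_len(n)) {
    set.seed(substream_seed(config$seed, i))
    x[i] <- stats::runif(1)
    y[i] <- stats::runif(1)
    mu[i] <- stats::runif(1, config$log_volume_mean_range[1L],
                          config$log_volume_mean_range[2L])
    sdl[i] <- config$cv_intercept *
      exp(config$cv_slope_logvolume * (mu[i] - mu_c) +
            config$cv_coeff_x * (x[i] - 0.5) +
            config$cv_coeff_y * (y[i] - 0.5))
    lv <- stats::rnorm(length(gels),
                       mean = mu[i] + ifelse(kd, log(fold[i]), 0),
                       sd = sdl[i])
    v <- exp(lv)
    if (config$dropout_rate > 0) {
      v[stats::runif(length(v)) < config$dropout_rate] <- 0
    }
    vols[i, ] <- v
  }
  ids <- sprintf("spot_%04d", seq_len(n))
  list(table = spot_table(ids, x, y, config$gradient, vols,
                          normalized = FALSE),
       truth = data.frame(spot_id = ids,
                          true_log_mean = mu,
                          true_mean_volume = exp(mu),
                          true_fold = fold,
                          true_log_sd = sdl,
                          stringsAsFactors = FALSE))
}

#' Generate paired synthetic MS hit lists for a mixed spot
#'
#' Allocates `total_spectra` MS/MS spectra to the proteins of a mixed spot
#' by a multinomial draw with weights proportional to
#' `share * length * effect` (longer proteins yield more detectable tryptic
#' peptides; `condition_effect` multiplies the knockdown weights only).
#' Per-spectrum ion scores are drawn from a two-component mixture so the
#' MASCOT-style confidence rule has both confident and marginal material to
#' chew on: with probability `score_high_prob` a score is
#' `20 + Exponential(mean = score_high_mean_excess)`, otherwise uniform on
#' `score_low_range`.
#'
#' @param spot_composition data frame with columns `accession`,
#'   `length` (residues) and `true_share` (summing to 1).
#' @param condition_effect per-protein abundance multiplier applied in the
#'   knockdown condition (recycled; 1 = no change).
#' @param total_spectra total matched spectra per condition (>= 1).
#' @param seed integer seed.
#' @param spot_id spot identifier carried into both lists.
#' @param score_high_prob mixture weight of the high-score component.
#' @param score_high_mean_excess mean of the exponential excess above 20.
#' @param score_low_range range of the low-score component.
#' @return list with elements `control` and `knockdown`, each a
#'   [hit_list()].
#' @export
generate_hit_tables <- function(spot_composition, condition_effect = 1,
                                total_spectra = 200L, seed = 1L,
                                spot_id = "spot_0001",
                                score_high_prob = 0.85,
                                score_high_mean_excess = 15,
                                score_low_range = c(5, 20)) {
  comp <- as.data.frame(spot_composition)
  if (!nrow(comp)) stop("empty spot composition", call. = FALSE)
  if (!all(c("accession", "length", "true_share") %in% names(comp))) {
    stop("'spot_composition' needs columns accession, length, true_share",
         call. = FALSE)
  }
  if (any(comp$length <= 0)) stop("protein lengths must be positive",
                                  call. = FALSE)
  if (abs(sum(comp$true_share) - 1) > 1e-6) {
    stop("'true_share' must sum to 1", call. = FALSE)
  }
  total_spectra <- check_count(total_spectra, "total_spectra", min = 1L)
  effect <- rep_len(condition_effect, nrow(comp))
  if (any(effect <= 0)) stop("'condition_effect' must be > 0", call. = FALSE)

  draw_one <- function(weights, condition, sub) {
    set.seed(substream_seed(seed, sub))
    counts <- as.integer(stats::rmultinom(1L, total_spectra,
                                          weights / sum(weights)))
    scores <- lapply(counts, function(k) {
      if (k == 0L) return(numeric())
      hi <- stats::runif(k) < score_high_prob
      s <- numeric(k)
      s[hi] <- 20 + stats::rexp(sum(hi), rate = 1 / score_high_mean_excess)
      s[!hi] <- stats::runif(sum(!hi), score_low_range[1L],
                             score_low_range[2L])
      round(s, 2)
    })
    hit_list(spot_id, condition, comp$accession, comp$length, counts,
             ion_scores = scores,
             unique_peptides = pmax(as.integer(counts > 0L),
                                    as.integer(ceiling(0.3 * counts))))
  }
  w0 <- comp$true_share * comp$length
  list(control = draw_one(w0, "control", 1L),
       knockdown = draw_one(w0 * effect, "knockdown", 2L))
}
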