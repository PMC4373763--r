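# End-to-end pipeline: normalize -> variability -> differential calls ->
# (optional) reference validation -> (optional) spot deconvolution, with a
# machine-readable provenance record and deterministic outputs.

#' Build a run configuration
#'
#' Either `spots` (a CSV path or a [spot_table()]) or `simulate` (a list of
#' [simulation_config()] arguments) must be given. A single master `seed`
#' fans out to stage-specific derived seeds, so one integer reproduces the
#' whole run.
#'
#' @param spots spot-table CSV path or a `spot_table` (optional).
#' @param simulate list of [simulation_config()] arguments (optional).
#' @param hits_control,hits_knockdown hit-table TSV paths (optional; both
#'   or neither).
#' @param normalize_method `"total-volume"` or `"none"` (accept the input
#'   as already normalized).
#' @param n_boot,subgroup_sizes,quantile bootstrap settings, see
#'   [bootstrap_settings()].
#' @param alpha FDR level for the differential calls.
#' @param scale `"log"` or `"raw"` test scale.
#' @param min_ratio,pseudocount triage settings, see [triage_spot()].
#' @param seed master integer seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(spots = NULL, simulate = NULL,
                       hits_control = NULL, hits_knockdown = NULL,
                       normalize_method = c("total-volume", "none"),
                       n_boot = 1000L, subgroup_sizes = c(7L, 7L),
                       quantile = 0.95, alpha = 0.05,
                       scale = c("log", "raw"),
                       min_ratio = 1.5, pseudocount = 0.5, seed = 1L) {
  normalize_method <- match.arg(normalize_method)
  scale <- match.arg(scale)
  if (is.null(spots) && is.null(simulate)) {
    stop("one of 'spots' or 'simulate' is required", call. = FALSE)
  }
  if (xor(is.null(hits_control), is.null(hits_knockdown))) {
    stop("'hits_control' and 'hits_knockdown' must be given together",
         call. = FALSE)
  }
  structure(list(spots = spots, simulate = simulate,
                 hits_control = hits_control,
                 hits_knockdown = hits_knockdown,
                 normalize_method = normalize_method,
                 n_boot = n_boot, subgroup_sizes = subgroup_sizes,
                 quantile = quantile, alpha = alpha, scale = scale,
                 min_ratio = min_ratio, pseudocount = pseudocount,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' @param path JSON file whose fields match the [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  args <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(args$simulate)) args$simulate <- as.list(args$simulate)
  do.call(run_config, args)
}

config_fingerprint <- function(config) {
  plain <- config
  if (inherits(plain$spots, "spot_table")) plain$spots <- "<in-memory>"
  config_hash(jsonlite::toJSON(unclass(plain), auto_unbox = TRUE,
                               null = "null", force = TRUE))
}

#' Run the full differential-display pipeline
#'
#' Executes normalize -> variability -> differential calls -> (optional)
#' reference validation -> (optional) deconvolution, writing every stage
#' output plus a run summary and a provenance record to `out_dir`. Outputs
#' carry the seed and a configuration fingerprint in commented headers and
#' contain no timestamps, so identical configurations rerun byte-for-byte
#' identically. A failing stage aborts with its name and leaves a `FAILED`
#' marker file next to the partial outputs.
#'
#' @param config a [run_config()] or a JSON path for [read_run_config()].
#' @param out_dir output directory (created if needed).
#' @return the run summary, invisibly: list with counts of spots analyzed,
#'   candidates, validated, and the up/down split.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- config_fingerprint(config)
  stamp <- sprintf("seed: %d; config: %s", config$seed, fp)
  fail <- function(stage, e) {
    writeLines(sprintf("stage: %s\nerror: %s", stage, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) fail(name, e))
  }
  unlink(file.path(out_dir, "FAILED"))

  # -- input ----------------------------------------------------------------
  truth <- NULL
  table <- stage("input", {
    if (!is.null(config$simulate)) {
      args <- config$simulate
      if (is.null(args$seed)) args$seed <- substream_seed(config$seed, 1L)
      sim <- generate_spot_table(do.call(simulation_config, args))
      truth <- sim$truth
      utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
                       row.names = FALSE, quote = FALSE)
      sim$table
    } else if (inherits(config$spots, "spot_table")) {
      config$spots
    } else {
      read_spot_table(config$spots)
    }
  })

  # -- normalize ------------------------------------------------------------
  table <- stage("normalize", {
    if (config$normalize_method == "total-volume") {
      norm <- normalize_total_volume(table)
      utils::write.csv(
        data.frame(gel = names(norm$report$scale_factor),
                   scale_factor = norm$report$scale_factor,
                   norm$report$post, row.names = NULL),
        file.path(out_dir, "normalization_report.csv"), row.names = FALSE,
        quote = FALSE)
      norm$table
    } else {
      table$normalized <- TRUE
      table
    }
  })
  write_spot_table(table, file.path(out_dir, "normalized_spots.csv"),
                   comments = stamp)
  qc <- boxplot_summary(table)
  if (any(qc$flagged)) {
    message("QC: flagged gel(s): ",
            paste(qc$gel[qc$flagged], collapse = ", "))
  }

  # -- variability ----------------------------------------------------------
  profile <- stage("variability", {
    settings <- bootstrap_settings(
      n_boot = config$n_boot, subgroup_sizes = config$subgroup_sizes,
      quantile = config$quantile, seed = substream_seed(config$seed, 2L))
    fit_threshold_glm(estimate_variability(table, settings))
  })
  write_variability_profile(profile,
                            file.path(out_dir, "variability_profile.csv"),
                            comments = stamp)

  # -- differential calls ---------------------------------------------------
  de <- stage("detest", {
    select_differential(table, profile, alpha = config$alpha,
                        scale = config$scale)
  })

  # -- reference validation -------------------------------------------------
  if ("wildtype" %in% table$group_of_gel) {
    de <- stage("validate", validate_against_reference(de, table))
  }
  write_de_result(de, file.path(out_dir, "de_results.csv"),
                  comments = stamp)

  # -- deconvolution --------------------------------------------------------
  triage <- NULL
  if (!is.null(config$hits_control)) {
    triage <- stage("deconvolve", {
      hc <- read_hit_table(config$hits_control)
      hk <- read_hit_table(config$hits_knockdown)
      spot_of <- function(nm) sub("\\.(control|knockdown)$", "", nm)
      shared_spots <- intersect(spot_of(names(hc)), spot_of(names(hk)))
      out <- list()
      for (sid in shared_spots) {
        i <- match(sid, de$spot_id)
        if (is.na(i)) next
        out[[sid]] <- triage_spot(hc[[paste0(sid, ".control")]],
                                  hk[[paste0(sid, ".knockdown")]],
                                  spot_direction = de$direction[i],
                                  min_ratio = config$min_ratio,
                                  pseudocount = config$pseudocount)
      }
      out
    })
    tri_df <- do.call(rbind, lapply(triage, as.data.frame))
    utils::write.csv(tri_df, file.path(out_dir, "triage.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(wb_worklist(triage), file.path(out_dir, "worklist.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  # -- summary + provenance -------------------------------------------------
  summary <- list(
    gradient = table$gradient[1L],
    n_spots = length(table$spot_id),
    n_tested = nrow(de),
    n_candidates = sum(de$selected),
    n_validated = sum(de$validated),
    n_up = sum(de$selected & de$direction == "up"),
    n_down = sum(de$selected & de$direction == "down"),
    flagged_gels = qc$gel[qc$flagged],
    n_triaged_spots = if (is.null(triage)) 0L else length(triage))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  provenance <- list(
    package = "geldd",
    version = as.character(utils::packageVersion("geldd")),
    seed = config$seed,
    config_fingerprint = fp,
    config = unclass(config_fingerprintable(config)))
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  message(sprintf(
    "%d spots analyzed, %d tested, %d candidates (%d up / %d down), %d validated",
    summary$n_spots, summary$n_tested, summary$n_candidates,
    summary$n_up, summary$n_down, summary$n_validated))
  invisible(summary)
}

config_fingerprintable <- function(config) {
  plain <- unclass(config)
  if (inherits(plain$spots, "spot_table")) plain$spots <- "<in-memory>"
  plain
}
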