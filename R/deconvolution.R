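# Spot deconvolution: MASCOT-style confidence filtering, spectral counting
# with NSAF, and triage of mixed spots into concordant / discordant /
# needs-Western-blot categories.

#' MASCOT-style hit confidence rule
#'
#' A protein identification is considered confident when it is supported by
#' at least three MS/MS spectra with peptide ion scores above 20, or two
#' spectra with scores higher than 40. An empty score list is not
#' confident. Adding a spectrum can never make a confident hit unconfident.
#'
#' @param ion_scores numeric vector of per-spectrum ion scores.
#' @return logical scalar.
#' @export
confident_hit <- function(ion_scores) {
  s <- as.numeric(ion_scores)
  if (any(!is.finite(s))) stop("ion scores must be finite", call. = FALSE)
  sum(s > 20) >= 3L || sum(s > 40) >= 2L
}

#' Compute NSAF for a hit list
#'
#' The spectral abundance factor of a protein is its spectral count divided
#' by its sequence length, `SAF = SpC / L`; the normalized SAF divides by
#' the sum over the list, so NSAF values are length-corrected relative
#' abundances summing to 1 over the proteins with at least one spectrum.
#' Entries with zero spectra get NSAF 0.
#'
#' @param hits a [hit_list()].
#' @return the hit list with its `nsaf` column filled in.
#' @export
compute_nsaf <- function(hits) {
  stopifnot(inherits(hits, "hit_list"))
  if (all(hits$matched_spectra == 0L)) {
    stop("all spectral counts are zero: no abundance information",
         call. = FALSE)
  }
  saf <- hits$matched_spectra / hits$protein_length
  hits$nsaf <- saf / sum(saf)
  hits
}

#' Triage one mixed spot by spectral abundance
#'
#' Compares the confident protein identifications of a spot between the
#' two conditions and asks which protein, if any, moves in the direction
#' the 2DE spot itself moved. Both lists are confidence-filtered
#' ([confident_hit()]) and their NSAF recomputed on the confident subset.
#'
#' For each accession confident in both conditions the knockdown/control
#' NSAF ratio is formed (zero spectral counts replaced by `pseudocount`
#' before the SAF computation); the verdict is:
#'
#' * `concordant_regulated` — ratio `>= min_ratio` with spot direction up,
#'   or `<= 1/min_ratio` with direction down: the spectral data point at
#'   this protein as the carrier of the spot's regulation;
#' * `discordant_flag_wb` — the ratio crosses the cutoff in the direction
#'   *opposite* to the spot: needs Western-blot confirmation;
#' * `unchanged` — otherwise.
#'
#' Accessions confident in only one condition cannot be ratioed; the major
#' such hit (highest NSAF in its condition) is flagged
#' `single_sample_flag_wb`, the remaining ones are `unchanged`.
#'
#' @param control_hits,knockdown_hits [hit_list()] objects for the spot.
#' @param spot_direction `"up"` or `"down"` from the DE pipeline.
#' @param min_ratio NSAF ratio regarded as a real change (default 1.5).
#' @param pseudocount replacement for zero spectral counts when forming
#'   ratios (default 0.5).
#' @return a `spot_triage`: data frame with columns `spot_id`, `accession`,
#'   `verdict`, `nsaf_control`, `nsaf_knockdown`, `nsaf_ratio`,
#'   `count_control`, `count_knockdown`, `direction`.
#' @export
triage_spot <- function(control_hits, knockdown_hits, spot_direction,
                        min_ratio = 1.5, pseudocount = 0.5) {
  stopifnot(inherits(control_hits, "hit_list"),
            inherits(knockdown_hits, "hit_list"))
  spot_direction <- match.arg(spot_direction, c("up", "down"))
  if (min_ratio <= 1) stop("'min_ratio' must be > 1", call. = FALSE)
  if (!nrow(control_hits) && !nrow(knockdown_hits)) {
    stop("both hit lists are empty", call. = FALSE)
  }
  spot_id <- attr(control_hits, "spot_id")

  conf_subset <- function(h) {
    keep <- vapply(h$ion_scores, confident_hit, logical(1L))
    h[keep, , drop = FALSE]
  }
  # NSAF with pseudocounted zeros, for ratio formation
  nsaf_pc <- function(counts, lengths) {
    cts <- ifelse(counts == 0, pseudocount, counts)
    saf <- cts / lengths
    saf / sum(saf)
  }
  ctrl <- conf_subset(control_hits)
  kd <- conf_subset(knockdown_hits)
  ctrl_nsaf <- if (nrow(ctrl)) nsaf_pc(ctrl$matched_spectra,
                                       ctrl$protein_length) else numeric()
  kd_nsaf <- if (nrow(kd)) nsaf_pc(kd$matched_spectra,
                                   kd$protein_length) else numeric()

  shared <- intersect(ctrl$accession, kd$accession)
  only_ctrl <- setdiff(ctrl$accession, kd$accession)
  only_kd <- setdiff(kd$accession, ctrl$accession)

  rows <- list()
  for (acc in sort(shared)) {
    i <- match(acc, ctrl$accession)
    j <- match(acc, kd$accession)
    ratio <- kd_nsaf[j] / ctrl_nsaf[i]
    verdict <- if ((ratio >= min_ratio && spot_direction == "up") ||
                   (ratio <= 1 / min_ratio && spot_direction == "down")) {
      "concordant_regulated"
    } else if ((ratio >= min_ratio && spot_direction == "down") ||
               (ratio <= 1 / min_ratio && spot_direction == "up")) {
      "discordant_flag_wb"
    } else "unchanged"
    rows[[length(rows) + 1L]] <- data.frame(
      spot_id = spot_id, accession = acc, verdict = verdict,
      nsaf_control = ctrl_nsaf[i], nsaf_knockdown = kd_nsaf[j],
      nsaf_ratio = ratio,
      count_control = ctrl$matched_spectra[i],
      count_knockdown = kd$matched_spectra[j],
      direction = spot_direction, stringsAsFactors = FALSE)
  }
  single <- function(accs, h, nsaf, cond) {
    if (!length(accs)) return()
    nz <- nsaf[match(accs, h$accession)]
    major <- accs[which.max(nz)]
    for (acc in sort(accs)) {
      i <- match(acc, h$accession)
      rows[[length(rows) + 1L]] <<- data.frame(
        spot_id = spot_id, accession = acc,
        verdict = if (acc == major) "single_sample_flag_wb" else "unchanged",
        nsaf_control = if (cond == "control") nsaf[i] else NA_real_,
        nsaf_knockdown = if (cond == "knockdown") nsaf[i] else NA_real_,
        nsaf_ratio = NA_real_,
        count_control = if (cond == "control") h$matched_spectra[i]
                        else NA_integer_,
        count_knockdown = if (cond == "knockdown") h$matched_spectra[i]
                          else NA_integer_,
        direction = spot_direction, stringsAsFactors = FALSE)
    }
  }
  single(only_ctrl, ctrl, ctrl_nsaf, "control")
  single(only_kd, kd, kd_nsaf, "knockdown")
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(spot_id = character(), accession = character(),
               verdict = character(), nsaf_control = numeric(),
               nsaf_knockdown = numeric(), nsaf_ratio = numeric(),
               count_control = integer(), count_knockdown = integer(),
               direction = character(), stringsAsFactors = FALSE)
  structure(out, class = c("spot_triage", "data.frame"))
}

#' Collect the Western-blot worklist from triage verdicts
#'
#' All `discordant_flag_wb` and `single_sample_flag_wb` entries across
#' spots, deduplicated by (spot, accession), with the flag preserved as the
#' reason.
#'
#' @param triage a `spot_triage` or a list of them.
#' @return data frame with columns `spot_id`, `accession`, `reason`.
#' @export
wb_worklist <- function(triage) {
  if (inherits(triage, "spot_triage")) triage <- list(triage)
  all_rows <- do.call(rbind, lapply(triage, as.data.frame))
  flags <- c("discordant_flag_wb", "single_sample_flag_wb")
  if (is.null(all_rows) || !nrow(all_rows)) {
    return(data.frame(spot_id = character(), accession = character(),
                      reason = character(), stringsAsFactors = FALSE))
  }
  w <- all_rows[all_rows$verdict %in% flags,
                c("spot_id", "accession", "verdict")]
  names(w)[3L] <- "reason"
  w <- w[!duplicated(w[, c("spot_id", "accession")]), , drop = FALSE]
  rownames(w) <- NULL
  w
}
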