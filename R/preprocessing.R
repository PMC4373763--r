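# Preprocessing: total-volume normalization, box-plot style QC summaries,
# and the blot-style relative-expression ratio.

#' Normalize a spot table to equal total volume per gel
#'
#' Scales every gel column so that all column sums equal the mean
#' pre-normalization total. Relative spot proportions within a gel are
#' untouched (a single positive factor per gel), which is the property the
#' downstream fold-change machinery relies on. The operation is idempotent:
#' normalizing an already-normalized table leaves it unchanged (factors 1).
#'
#' @param table a [spot_table()].
#' @return list with elements `table` (normalized [spot_table()]) and
#'   `report` (a `normalization_report`: per-gel scale factor and pre/post
#'   five-number summaries of log10 volumes, see [boxplot_summary()]).
#' @export
normalize_total_volume <- function(table) {
  stopifnot(inherits(table, "spot_table"))
  totals <- colSums(table$volumes)
  if (any(totals <= 0)) {
    stop(sprintf("gel '%s' has zero total volume",
                 names(totals)[totals <= 0][1L]), call. = FALSE)
  }
  target <- mean(totals)
  factors <- target / totals
  pre <- fivenum_log10(table$volumes)
  out <- table
  out$volumes <- sweep(table$volumes, 2L, factors, `*`)
  out$normalized <- TRUE
  post <- fivenum_log10(out$volumes)
  report <- structure(
    list(scale_factor = factors, pre = pre, post = post),
    class = "normalization_report")
  list(table = out, report = report)
}

# Per-gel five-number summary of log10 of the positive volumes.
fivenum_log10 <- function(volumes) {
  s <- apply(volumes, 2L, function(v) {
    v <- v[v > 0]
    stats::fivenum(log10(v))
  })
  rownames(s) <- c("min", "q1", "median", "q3", "max")
  t(s)
}

#' @export
print.normalization_report <- function(x, ...) {
  cat("normalization_report\n  scale factors:\n")
  print(round(x$scale_factor, 4))
  invisible(x)
}

#' Box-plot style QC summary of a normalized spot table
#'
#' The classical visual check after normalization is that the per-gel
#' box-plots of log volumes line up. This returns the per-gel five-number
#' summary of log10 volumes and flags any gel whose median deviates from
#' the median of gel medians by more than `multiplier` times the median
#' per-gel IQR.
#'
#' @param table a normalized [spot_table()].
#' @param multiplier flagging multiple of the IQR (default 1.5, the
#'   box-plot whisker convention).
#' @return a `boxplot_report`: data frame with columns `gel`, `min`, `q1`,
#'   `median`, `q3`, `max`, `flagged`.
#' @export
boxplot_summary <- function(table, multiplier = 1.5) {
  stopifnot(inherits(table, "spot_table"))
  if (!table$normalized) {
    stop("boxplot_summary expects a normalized table", call. = FALSE)
  }
  s <- fivenum_log10(table$volumes)
  med <- s[, "median"]
  iqr <- s[, "q3"] - s[, "q1"]
  center <- stats::median(med)
  scale <- stats::median(iqr)
  flagged <- abs(med - center) > multiplier * scale
  out <- data.frame(gel = rownames(s), s, flagged = flagged,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("boxplot_report", "data.frame")
  out
}

#' Relative expression from a blot band and total-protein stain
#'
#' The ratio between a Western-blot band intensity and the total protein
#' content of the lane (e.g. from PonceauS staining), the normalization
#' used for blot-based validation of gel findings.
#'
#' @param band_intensity non-negative band intensity.
#' @param total_protein_stain strictly positive total-protein signal.
#' @return `band_intensity / total_protein_stain` (vectorized).
#' @export
relative_expression <- function(band_intensity, total_protein_stain) {
  if (any(!is.finite(total_protein_stain) | total_protein_stain <= 0)) {
    stop("'total_protein_stain' must be strictly positive", call. = FALSE)
  }
  if (any(!is.finite(band_intensity) | band_intensity < 0)) {
    stop("'band_intensity' must be non-negative", call. = FALSE)
  }
  band_intensity / total_protein_stain
}
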