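# SpotHitList: per-spot, per-condition protein identifications from MS.

#' Construct a spot hit list
#'
#' One MS hit list for a single excised spot under a single condition.
#' Each entry is a candidate protein with its database sequence length
#' (residues), the number of matched MS/MS spectra, the per-spectrum ion
#' scores, and the number of unique peptides.
#'
#' @param spot_id spot identifier.
#' @param condition `"control"` or `"knockdown"`.
#' @param accession character vector, unique within the list.
#' @param protein_length positive integer sequence lengths (residues).
#' @param matched_spectra non-negative integer spectral counts.
#' @param ion_scores list of numeric vectors, one per entry.
#' @param unique_peptides non-negative integer counts (optional).
#' @return an object of class `hit_list`: a data frame with one row per
#'   protein entry, the `ion_scores` held as a list column, and an `nsaf`
#'   column that is `NA` until [compute_nsaf()] is called.
#' @export
hit_list <- function(spot_id, condition, accession, protein_length,
                     matched_spectra, ion_scores,
                     unique_peptides = pmin(matched_spectra, 1L)) {
  condition <- match.arg(condition, c("control", "knockdown"))
  accession <- as.character(accession)
  if (anyDuplicated(accession)) {
    stop(sprintf("duplicated accession '%s' in hit list",
                 accession[duplicated(accession)][1L]), call. = FALSE)
  }
  if (any(protein_length <= 0 | protein_length != floor(protein_length))) {
    stop("protein lengths must be positive integers (residues)",
         call. = FALSE)
  }
  if (any(matched_spectra < 0)) stop("spectral counts must be >= 0",
                                     call. = FALSE)
  stopifnot(is.list(ion_scores), length(ion_scores) == length(accession))
  df <- data.frame(accession = accession,
                   protein_length = as.integer(protein_length),
                   matched_spectra = as.integer(matched_spectra),
                   unique_peptides = as.integer(unique_peptides),
                   nsaf = rep(NA_real_, length(accession)),
                   stringsAsFactors = FALSE)
  df$ion_scores <- lapply(ion_scores, as.numeric)
  structure(df, class = c("hit_list", "data.frame"),
            spot_id = as.character(spot_id), condition = condition)
}

#' @export
print.hit_list <- function(x, ...) {
  cat(sprintf("hit_list: spot '%s', condition '%s', %d proteins\n",
              attr(x, "spot_id"), attr(x, "condition"), nrow(x)))
  print.data.frame(
    data.frame(x[, c("accession", "protein_length", "matched_spectra",
                     "unique_peptides", "nsaf")]),
    row.names = FALSE)
  invisible(x)
}

#' Write MS hit lists as TSV
#'
#' One row per (spot, condition, protein): columns `spot_id`, `condition`,
#' `accession`, `length`, `spectra`, `unique_peptides` and the per-spectrum
#' ion scores semicolon-joined in `ion_scores`.
#'
#' @param hits a `hit_list` or a list of them.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  if (inherits(hits, "hit_list")) hits <- list(hits)
  rows <- lapply(hits, function(h) {
    data.frame(spot_id = attr(h, "spot_id"),
               condition = attr(h, "condition"),
               accession = h$accession,
               length = h$protein_length,
               spectra = h$matched_spectra,
               unique_peptides = h$unique_peptides,
               ion_scores = vapply(h$ion_scores, function(s) {
                 paste(formatC(s, digits = 6, format = "g"), collapse = ";")
               }, character(1L)),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read MS hit lists from TSV
#'
#' Inverse of [write_hit_table()]; returns one `hit_list` per
#' (spot, condition) pair found in the file.
#'
#' @param path TSV file path.
#' @return named list of `hit_list` objects, names `"<spot_id>.<condition>"`.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("hit table file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("spot_id", "condition", "accession", "length", "spectra",
                "ion_scores")
  if (!all(required %in% names(df))) {
    stop(sprintf("malformed hit table: missing column(s) %s",
                 paste(setdiff(required, names(df)), collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(df$unique_peptides)) df$unique_peptides <- pmin(df$spectra, 1L)
  key <- interaction(df$spot_id, df$condition, drop = TRUE)
  out <- lapply(split(df, key), function(d) {
    hit_list(d$spot_id[1L], d$condition[1L], d$accession, d$length,
             d$spectra,
             ion_scores = lapply(strsplit(as.character(d$ion_scores), ";",
                                          fixed = TRUE),
                                 function(s) as.numeric(s[nzchar(s)])),
             unique_peptides = d$unique_peptides)
  })
  out[order(names(out))]
}
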