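# SpotTable: the central spots x gels volume container.
#
# Gel columns are named "<group>_<replicate>" with group one of
# "control", "knockdown", "wildtype"; the group assignment is carried as a
# named character vector alongside the matrix so a gel is never ambiguous.

VALID_GROUPS <- c("control", "knockdown", "wildtype")

#' Construct a spot table
#'
#' A `spot_table` holds normalized or raw spot volumes for one IPG gradient:
#' one row per detected spot with its gel coordinates (unit square, `x`
#' increasing with pI, `y` with migration distance) and one column per gel.
#'
#' @param spot_id character vector of unique spot identifiers.
#' @param x,y numeric gel coordinates in `[0, 1]`.
#' @param gradient IPG gradient label (e.g. `"4-7"` or `"6-11"`), recycled.
#' @param volumes numeric matrix, spots x gels, non-negative; column names
#'   must follow the `<group>_<replicate>` convention.
#' @param group_of_gel named character vector mapping gel column name to
#'   group; derived from column names when omitted.
#' @param normalized logical flag: have the gel columns been scaled to a
#'   common total volume already?
#' @return an object of class `spot_table`.
#' @seealso [read_spot_table()], [write_spot_table()],
#'   [normalize_total_volume()]
#' @export
spot_table <- function(spot_id, x, y, gradient, volumes,
                       group_of_gel = NULL, normalized = FALSE) {
  spot_id <- as.character(spot_id)
  if (anyDuplicated(spot_id)) {
    dup <- spot_id[duplicated(spot_id)][1L]
    stop(sprintf("duplicated spot_id '%s'", dup), call. = FALSE)
  }
  volumes <- as.matrix(volumes)
  if (nrow(volumes) != length(spot_id)) {
    stop("'volumes' must have one row per spot", call. = FALSE)
  }
  if (is.null(colnames(volumes))) {
    stop("'volumes' must have gel column names", call. = FALSE)
  }
  if (any(!is.finite(volumes)) || any(volumes < 0)) {
    bad <- which(!is.finite(volumes) | volumes < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative or non-finite volume for spot '%s' in gel '%s'",
                 spot_id[bad[1L]], colnames(volumes)[bad[2L]]), call. = FALSE)
  }
  if (is.null(group_of_gel)) {
    group_of_gel <- gel_groups_from_names(colnames(volumes))
  }
  if (!all(names(group_of_gel) == colnames(volumes))) {
    stop("'group_of_gel' must be named exactly by the gel columns",
         call. = FALSE)
  }
  if (!all(group_of_gel %in% VALID_GROUPS)) {
    stop(sprintf("gel groups must be one of: %s",
                 paste(VALID_GROUPS, collapse = ", ")), call. = FALSE)
  }
  stopifnot(length(x) == length(spot_id), length(y) == length(spot_id))
  if (any(x < 0 | x > 1) || any(y < 0 | y > 1)) {
    stop("spot coordinates must lie in the unit square", call. = FALSE)
  }
  structure(
    list(spot_id = spot_id,
         x = as.numeric(x), y = as.numeric(y),
         gradient = rep_len(as.character(gradient), length(spot_id)),
         volumes = volumes,
         group_of_gel = group_of_gel,
         normalized = isTRUE(normalized)),
    class = "spot_table")
}

gel_groups_from_names <- function(gels) {
  grp <- sub("_[0-9]+$", "", gels)
  if (!all(grp %in% VALID_GROUPS)) {
    stop(sprintf("cannot derive groups from gel names: %s",
                 paste(gels[!grp %in% VALID_GROUPS], collapse = ", ")),
         call. = FALSE)
  }
  stats::setNames(grp, gels)
}

#' @export
print.spot_table <- function(x, ...) {
  grp <- table(x$group_of_gel)
  cat(sprintf("spot_table: %d spots x %d gels (gradient %s, %s)\n",
              length(x$spot_id), ncol(x$volumes), x$gradient[1L],
              if (x$normalized) "normalized" else "raw"))
  cat("  gels:", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.spot_table <- function(x) dim(x$volumes)

# Gel column names belonging to one group.
gels_of_group <- function(table, group) {
  names(table$group_of_gel)[table$group_of_gel == group]
}

# Volume sub-matrix of one group (spots x replicates).
group_volumes <- function(table, group) {
  table$volumes[, gels_of_group(table, group), drop = FALSE]
}

#' Write a spot table to CSV
#'
#' The dialect is self-describing: `#`-prefixed header lines carry the
#' gradient and normalization state (plus any provenance comments supplied),
#' then a regular CSV with columns `spot_id, x, y, gradient` followed by one
#' column per gel named `<group>_<replicate>`.
#'
#' @param table a [spot_table()].
#' @param path output file path.
#' @param comments optional extra comment lines (without the leading `#`).
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(table, path, comments = character()) {
  stopifnot(inherits(table, "spot_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# geldd spot table v1",
               sprintf("# normalized: %s",
                       if (table$normalized) "true" else "false"),
               if (length(comments)) paste("#", comments)), con)
  df <- data.frame(spot_id = table$spot_id,
                   x = table$x, y = table$y, gradient = table$gradient,
                   table$volumes, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spot table from CSV
#'
#' Parses the dialect written by [write_spot_table()]. Malformed input is
#' rejected with an error naming the offending spot, row or gel: missing
#' required columns, duplicated `spot_id`, or negative volumes.
#'
#' @param path CSV file path.
#' @return a [spot_table()].
#' @export
read_spot_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("spot table file not found: %s", path), call. = FALSE)
  }
  header <- readLines(path, n = 25L)
  normalized <- any(grepl("^#\\s*normalized:\\s*true\\s*$", header))
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE)
  required <- c("spot_id", "x", "y", "gradient")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("malformed spot table header: missing column(s) %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  gels <- setdiff(names(df), required)
  if (!length(gels)) stop("spot table has no gel volume columns",
                          call. = FALSE)
  if (anyDuplicated(df$spot_id)) {
    stop(sprintf("duplicated spot_id '%s'",
                 df$spot_id[duplicated(df$spot_id)][1L]), call. = FALSE)
  }
  vols <- as.matrix(df[, gels, drop = FALSE])
  if (any(!is.finite(vols)) || any(vols < 0)) {
    bad <- which(!is.finite(vols) | vols < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "negative or non-finite volume at row %d (spot '%s'), gel '%s'",
      bad[1L], df$spot_id[bad[1L]], gels[bad[2L]]), call. = FALSE)
  }
  spot_table(df$spot_id, df$x, df$y, df$gradient, vols,
             normalized = normalized)
}
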