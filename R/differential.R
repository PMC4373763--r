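# Differential expression: Welch tests, BH-FDR adjustment, fold changes,
# the dual selection criterion, and reference-line validation.

#' Welch two-sample t-test
#'
#' The unequal-variance two-sample t-test with Welch-Satterthwaite degrees
#' of freedom, computed directly from the group summaries. The statistic is
#' `t = (mean(a) - mean(b)) / sqrt(s_a^2/n_a + s_b^2/n_b)` (sign fixed by
#' argument order). With `tails = "one"` the alternative is oriented by the
#' observed sign, so the one-tailed p is half the two-tailed p (or 0.5 when
#' `t == 0`).
#'
#' By convention, two groups with zero variance and equal means give
#' `t = 0, p = 1`; zero variance with unequal means gives `p = 0`.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param tails `"two"` (discovery default) or `"one"` (validation use).
#' @return list with elements `t`, `df`, `p`.
#' @export
welch_test <- function(group_a, group_b, tails = c("two", "one")) {
  tails <- match.arg(tails)
  a <- as.numeric(group_a)
  b <- as.numeric(group_b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("groups must be finite", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  va <- stats::var(a) / na
  vb <- stats::var(b) / nb
  delta <- mean(a) - mean(b)
  se2 <- va + vb
  if (se2 == 0) {
    t <- if (delta == 0) 0 else sign(delta) * Inf
    df <- na + nb - 2
  } else {
    t <- delta / sqrt(se2)
    df <- se2^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  }
  p2 <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
  p <- if (tails == "two") p2 else p2 / 2
  list(t = t, df = df, p = min(p, 1))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: with `m` tests and order statistics `p_(j)`,
#' `adj_(i) = min_{j >= i} min(1, m * p_(j) / j)`. Adjusted values are
#' always `>=` the raw ones and monotone along the sorted raw p-values.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the original order.
#' @export
adjust_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  if (m == 0L) return(numeric())
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Fold change of group means
#'
#' Knockdown mean over control mean — values below 1 are down-regulated in
#' the knockdown, values above 1 up-regulated.
#'
#' @param control_mean,knockdown_mean strictly positive group means
#'   (vectorized).
#' @return `knockdown_mean / control_mean`.
#' @export
fold_change <- function(control_mean, knockdown_mean) {
  if (any(!is.finite(control_mean) | control_mean <= 0) ||
      any(!is.finite(knockdown_mean) | knockdown_mean <= 0)) {
    stop("group means must be strictly positive", call. = FALSE)
  }
  knockdown_mean / control_mean
}

#' Dual-criterion differential expression calls
#'
#' For every spot with valid data in both groups, computes the
#' knockdown/control fold change of mean volumes, a Welch t-test (on log
#' volumes by default — consistent with the multiplicative fold criterion —
#' or on the raw scale with `scale = "raw"`), BH-FDR-adjusted p-values
#' across all tested spots, and the two selection criteria:
#'
#' * `passes_fdr`: adjusted p `<= alpha`;
#' * `passes_threshold`: orientation-free fold `max(fold, 1/fold)` at least
#'   the spot's predicted intrinsic-variability threshold.
#'
#' A spot is `selected` only when it fulfils **both** simultaneously, so
#' the call set is never less conservative than FDR alone. Spots with any
#' non-positive volume in a tested group are excluded with a warning.
#'
#' @param table a normalized [spot_table()] with control and knockdown gels.
#' @param profile a [fit_threshold_glm()] profile; thresholds are taken
#'   from its fitted spots, and every tested spot must have one (error
#'   listing the missing ids otherwise).
#' @param alpha FDR level (default 0.05).
#' @param scale `"log"` (default) or `"raw"`: scale on which the Welch test
#'   is run.
#' @param tails tails of the discovery test (default two-tailed).
#' @return a `de_result`: data frame with columns `spot_id`, `fold`,
#'   `welch_t`, `welch_df`, `p_raw`, `p_fdr`, `threshold`, `passes_fdr`,
#'   `passes_threshold`, `selected`, `direction`, `validated`; excluded
#'   spot ids in `attr(, "excluded")`.
#' @export
select_differential <- function(table, profile, alpha = 0.05,
                                scale = c("log", "raw"),
                                tails = c("two", "one")) {
  scale <- match.arg(scale)
  tails <- match.arg(tails)
  stopifnot(inherits(table, "spot_table"),
            inherits(profile, "variability_profile"),
            alpha > 0, alpha < 1)
  ctrl <- group_volumes(table, "control")
  kd <- group_volumes(table, "knockdown")
  if (!ncol(ctrl) || !ncol(kd)) {
    stop("table needs both control and knockdown gels", call. = FALSE)
  }
  ok <- apply(ctrl, 1L, function(v) all(v > 0)) &
    apply(kd, 1L, function(v) all(v > 0))
  if (!all(ok)) {
    warning(sprintf("%d spot(s) with non-positive volumes excluded: %s",
                    sum(!ok),
                    paste(utils::head(table$spot_id[!ok], 5L),
                          collapse = ", ")), call. = FALSE)
  }
  keep <- which(ok)
  ids <- table$spot_id[keep]

  thr_map <- stats::setNames(profile$data$predicted_threshold,
                             profile$data$spot_id)
  missing_thr <- setdiff(ids, names(thr_map))
  if (length(missing_thr)) {
    stop(sprintf("no threshold available for spot(s): %s",
                 paste(utils::head(missing_thr, 10L), collapse = ", ")),
         call. = FALSE)
  }
  thr <- unname(thr_map[ids])

  cm <- rowMeans(ctrl[keep, , drop = FALSE])
  km <- rowMeans(kd[keep, , drop = FALSE])
  fold <- fold_change(cm, km)

  tests <- lapply(keep, function(i) {
    a <- kd[i, ]; b <- ctrl[i, ]
    if (scale == "log") { a <- log(a); b <- log(b) }
    welch_test(a, b, tails = tails)
  })
  t_stat <- vapply(tests, `[[`, numeric(1L), "t")
  t_df <- vapply(tests, `[[`, numeric(1L), "df")
  p_raw <- vapply(tests, `[[`, numeric(1L), "p")
  p_fdr <- adjust_fdr(p_raw)

  passes_fdr <- p_fdr <= alpha
  passes_threshold <- pmax(fold, 1 / fold) >= thr
  out <- data.frame(spot_id = ids,
                    fold = fold,
                    welch_t = t_stat,
                    welch_df = t_df,
                    p_raw = p_raw,
                    p_fdr = p_fdr,
                    threshold = thr,
                    passes_fdr = passes_fdr,
                    passes_threshold = passes_threshold,
                    selected = passes_fdr & passes_threshold,
                    direction = ifelse(fold > 1, "up", "down"),
                    validated = FALSE,
                    stringsAsFactors = FALSE)
  structure(out, class = c("de_result", "data.frame"),
            alpha = alpha, scale = scale,
            excluded = table$spot_id[!ok])
}

#' Validate selected spots against a reference line
#'
#' Candidates from [select_differential()] are confirmed against an
#' independent reference (e.g. non-transfected wild-type gels): a selected
#' spot is `validated` when the knockdown-vs-reference fold has the same
#' direction as the knockdown-vs-control fold **and** its one-tailed Welch
#' p-value is `<= alpha`. Non-selected spots are never validated; selected
#' spots without reference data are left unvalidated with a warning.
#'
#' @param de a `de_result` from [select_differential()].
#' @param reference a [spot_table()] containing `wildtype` and `knockdown`
#'   gels (typically the same table passed to [select_differential()]).
#' @param alpha significance level for the one-tailed confirmation test
#'   (defaults to the level stored in `de`).
#' @param scale test scale (defaults to the one stored in `de`).
#' @return `de` with its `validated` column filled in.
#' @export
validate_against_reference <- function(de, reference,
                                       alpha = attr(de, "alpha"),
                                       scale = attr(de, "scale")) {
  stopifnot(inherits(de, "de_result"), inherits(reference, "spot_table"))
  wt <- group_volumes(reference, "wildtype")
  kd <- group_volumes(reference, "knockdown")
  if (!ncol(wt)) stop("reference table has no wildtype gels", call. = FALSE)
  de$validated <- FALSE
  sel <- which(de$selected)
  if (!length(sel)) return(de)
  idx_map <- match(de$spot_id, reference$spot_id)
  no_ref <- character()
  for (i in sel) {
    j <- idx_map[i]
    w <- if (is.na(j)) numeric() else wt[j, ]
    k <- if (is.na(j)) numeric() else kd[j, ]
    if (is.na(j) || any(w <= 0) || any(k <= 0) || length(w) < 2L) {
      no_ref <- c(no_ref, de$spot_id[i])
      next
    }
    ref_fold <- mean(k) / mean(w)
    same_dir <- (de$direction[i] == "up" && ref_fold > 1) ||
      (de$direction[i] == "down" && ref_fold < 1)
    if (!same_dir) next
    a <- k; b <- w
    if (scale == "log") { a <- log(a); b <- log(b) }
    wt_test <- welch_test(a, b, tails = "one")
    de$validated[i] <- wt_test$p <= alpha
  }
  if (length(no_ref)) {
    warning(sprintf("selected spot(s) without usable reference data left unvalidated: %s",
                    paste(utils::head(no_ref, 10L), collapse = ", ")),
            call. = FALSE)
  }
  de
}

#' Write a differential-expression result table
#'
#' @param de a `de_result`.
#' @param path CSV output path.
#' @param comments optional comment lines for the CSV header.
#' @return `path`, invisibly.
#' @export
write_de_result <- function(de, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# geldd differential expression v1",
               sprintf("# alpha: %s; scale: %s",
                       attr(de, "alpha"), attr(de, "scale")),
               if (length(comments)) paste("#", comments)), con)
  utils::write.csv(as.data.frame(de), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
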