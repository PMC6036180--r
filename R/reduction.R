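# Response-blind feature reduction: near-zero-variance removal followed by
# iterative elimination of highly correlated feature pairs. Neither step
# reads the age column, which is what makes fitting the reduction once on
# the full table (rather than inside each training fold) defensible.

#' Drop constant and near-zero-variance features
#'
#' A column is removed when it is constant, or when the ratio of the most
#' common to the second most common value exceeds `freq_cut` AND the
#' percentage of unique values is below `unique_cut` (the standard
#' two-criterion near-zero-variance rule).
#'
#' @param table feature table (data frame; `subject_id`/`age`/`sex` key
#'   columns are passed through untouched).
#' @param freq_cut frequency ratio cutoff (default 95/5).
#' @param unique_cut percent-unique cutoff (default 10).
#' @return list with `table` (reduced) and `report` (a `reduction_report`).
#' @export
drop_low_variance <- function(table, freq_cut = 95 / 5, unique_cut = 10) {
  stop_if(nrow(table) < 2L, "need at least two subjects")
  feats <- setdiff(names(table), meta_columns())
  nzv <- vapply(feats, function(f) {
    x <- table[[f]]
    tab <- sort(tabulate(factor(x)), decreasing = TRUE)
    if (length(tab) == 1L) return(TRUE)  # constant
    ratio <- tab[1L] / tab[2L]
    pct_unique <- 100 * length(tab) / length(x)
    ratio > freq_cut && pct_unique < unique_cut
  }, TRUE)
  dropped <- feats[nzv]
  stop_if(length(dropped) == length(feats), "all feature columns removed")
  report <- structure(list(
    kept = setdiff(feats, dropped),
    dropped = if (length(dropped)) data.frame(
      feature = dropped, reason = "low_variance", stringsAsFactors = FALSE)
    else data.frame(feature = character(), reason = character()),
    threshold = NA_real_), class = "reduction_report")
  list(table = table[, !(names(table) %in% dropped), drop = FALSE],
       report = report)
}

#' Remove highly correlated features
#'
#' Iteratively locates the remaining feature pair with the highest absolute
#' Pearson correlation; while that correlation is at or above `cutoff`, the
#' member of the pair with the larger mean absolute correlation against all
#' remaining features is dropped. On ties (equal pair correlations, or
#' equal mean absolute correlations within a pair) the earlier column wins,
#' making the procedure deterministic. The surviving set contains no pair
#' with `|r| >= cutoff`.
#'
#' @param table feature table (data frame with numeric feature columns).
#' @param cutoff absolute correlation threshold (default 0.9).
#' @return list with `table` (reduced) and `report` (a `reduction_report`
#'   whose `dropped` entries carry the partner that triggered removal).
#' @export
find_correlated <- function(table, cutoff = 0.9) {
  stop_if(nrow(table) < 3L, "need at least three subjects")
  feats <- setdiff(names(table), meta_columns())
  x <- as.matrix(table[, feats, drop = FALSE])
  cm <- suppressWarnings(abs(cor(x)))
  if (anyNA(cm)) {
    warning("NA correlations (constant column?) treated as 0")
    cm[is.na(cm)] <- 0
  }
  diag(cm) <- 0
  p <- length(feats)
  alive <- rep(TRUE, p)
  rowsum_abs <- rowSums(cm)  # running sum of |r| against remaining columns

  # the correlation matrix never changes, so "the remaining pair with the
  # highest |r|" is simply the next entry of the pre-sorted candidate list
  # whose members are both still alive
  ut <- which(upper.tri(cm) & cm >= cutoff)
  ii <- (ut - 1L) %% p + 1L
  jj <- (ut - 1L) %/% p + 1L
  ord <- order(-cm[ut], ii, jj)  # ties -> earliest column pair first
  ii <- ii[ord]; jj <- jj[ord]

  drop_idx <- integer(); keep_idx <- integer()
  for (k in seq_along(ii)) {
    i <- ii[k]; j <- jj[k]
    if (!alive[i] || !alive[j]) next
    mi <- rowsum_abs[i]
    mj <- rowsum_abs[j]
    out <- if (mj > mi) j else i  # tie -> earlier column dropped
    keep <- if (out == i) j else i
    alive[out] <- FALSE
    rowsum_abs <- rowsum_abs - cm[, out]
    drop_idx <- c(drop_idx, out)
    keep_idx <- c(keep_idx, keep)
  }
  dropped <- feats[drop_idx]
  partner <- feats[keep_idx]

  report <- structure(list(
    kept = feats[alive],
    dropped = data.frame(
      feature = dropped,
      reason = if (length(partner)) paste0("correlated_with:", partner)
               else character(),
      stringsAsFactors = FALSE),
    threshold = cutoff), class = "reduction_report")
  list(table = table[, !(names(table) %in% dropped), drop = FALSE],
       report = report)
}

#' Full reduction pipeline
#'
#' [drop_low_variance()] followed by [find_correlated()], with the two
#' reports merged.
#'
#' @inheritParams drop_low_variance
#' @inheritParams find_correlated
#' @return list with `table` and `report`.
#' @export
reduce_features <- function(table, cutoff = 0.9, freq_cut = 95 / 5,
                            unique_cut = 10) {
  lv <- drop_low_variance(table, freq_cut, unique_cut)
  fc <- find_correlated(lv$table, cutoff)
  report <- structure(list(
    kept = fc$report$kept,
    dropped = rbind(lv$report$dropped, fc$report$dropped),
    threshold = cutoff), class = "reduction_report")
  list(table = fc$table, report = report)
}

#' @export
print.reduction_report <- function(x, ...) {
  cat(sprintf("<reduction_report> kept %d, dropped %d (threshold %s)\n",
              length(x$kept), nrow(x$dropped),
              ifelse(is.na(x$threshold), "-", x$threshold)))
  if (nrow(x$dropped) > 0L) {
    tab <- table(sub(":.*$", "", x$dropped$reason))
    for (r in names(tab)) cat(sprintf("  %s: %d\n", r, tab[[r]]))
  }
  invisible(x)
}
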