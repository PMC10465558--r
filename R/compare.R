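# Set comparison between DB and DB+SL identification results, and the
# feature-binned frequency analysis used to choose filter thresholds.

#' Compare DB and DB+SL identification key sets
#'
#' Spectrum-level set algebra between the valid PSMs of database searching
#' alone and of combined database + spectral-library searching: the common
#' keys, the DB-exclusive keys (found only without the library), and the
#' DB+SL-exclusive keys (gained by adding the library; the input to FPF).
#' Comparison is purely key-based: a spectrum identified by both searches is
#' common even if the peptide assignments disagree.
#'
#' @param db_keys,dbsl_keys Character vectors of [spectrum_key()]s.
#' @return A list of character vectors `common`, `db_exclusive`,
#'   `dbsl_exclusive`.
#' @export
compare_sets <- function(db_keys, dbsl_keys) {
  db_keys <- unique(as.character(db_keys))
  dbsl_keys <- unique(as.character(dbsl_keys))
  list(common = intersect(db_keys, dbsl_keys),
       db_exclusive = setdiff(db_keys, dbsl_keys),
       dbsl_exclusive = setdiff(dbsl_keys, db_keys))
}

#' Frequency of large-error PSMs across feature bins
#'
#' The threshold-finding analysis: bin PSMs by one spectral feature and
#' report, per bin, how many carry the "larger quantitation error" label and
#' the resulting frequency, `100 * count_large / count_total` percent. A
#' feature whose large-error frequency jumps across some value suggests that
#' value as a filter threshold (e.g. 13 of 21 PSMs at peptide length >= 25 is
#' 61.9%, against 24.6% below).
#'
#' @param features Feature table from [featurize()].
#' @param large_error_keys Character vector of keys labeled as large-error
#'   (see [label_large_error()]).
#' @param feature Name of the feature column to bin.
#' @param breaks Numeric vector of cut points; bins are
#'   `[b1, b2), [b2, b3), ...` with the last bin closed on the right.
#' @return A `data.frame` with `bin`, `count_large`, `count_total`,
#'   `frequency_pct` (`NA` for empty bins); PSMs with a missing feature value
#'   are excluded.
#' @export
frequency_by_feature <- function(features, large_error_keys, feature,
                                 breaks) {
  if (!feature %in% names(features))
    stop("unknown feature: ", feature)
  breaks <- sort(unique(as.numeric(breaks)))
  if (length(breaks) < 2L) stop("need at least two break points")
  x <- features[[feature]]
  ok <- !is.na(x)
  if (any(x[ok] < breaks[1] | x[ok] > breaks[length(breaks)]))
    stop("breaks do not cover the observed range of ", feature)
  bin <- cut(x[ok], breaks, right = FALSE, include.lowest = TRUE)
  # close the last bin on the right
  top <- x[ok] == breaks[length(breaks)]
  bin[top] <- levels(bin)[nlevels(bin)]
  is_large <- features$spectrum_key[ok] %in% large_error_keys
  count_total <- as.integer(table(bin))
  count_large <- as.integer(table(bin[is_large]))
  data.frame(
    bin = levels(bin),
    count_large = count_large,
    count_total = count_total,
    frequency_pct = ifelse(count_total > 0,
                           100 * count_large / count_total, NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Quartile summary of ARE values
#'
#' First quartile, median and third quartile of a set of ARE values, using
#' linear interpolation of order statistics (the default quantile
#' convention).
#'
#' @param ares Nonempty numeric vector.
#' @return Named numeric vector `c(q1, median, q3)`.
#' @export
ares_summary <- function(ares) {
  ares <- ares[!is.na(ares)]
  if (!length(ares)) stop("ares_summary needs at least one value")
  q <- stats::quantile(ares, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(q1 = q[1], median = q[2], q3 = q[3])
}
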