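# Reporter normalization, SumPsmIntensity protein quantitation, and the
# accuracy metrics: per-PSM/protein average relative error (ARE) and the
# coverage-versus-ARE AUC.

#' Median-normalize reporter-ion intensities
#'
#' Equalizes the channels of an isobaric experiment by scaling each channel
#' so that its median intensity across all identified spectra matches a
#' common reference. The reference is the median of the per-channel medians,
#' which keeps intensities on their original scale; since every ratio divides
#' one channel by another, the choice of reference does not affect ratios.
#' Missing reporter ions stay missing and are excluded from the medians.
#'
#' @param psms A PSM table with raw reporter columns.
#' @param design A [channel_design()].
#' @return The PSM table with reporter columns rescaled so all channel
#'   medians are equal.
#' @export
normalize_reporters <- function(psms, design) {
  rc <- reporter_cols(design)
  m <- reporter_matrix(psms, design)
  med <- apply(m, 2L, stats::median, na.rm = TRUE)
  dead <- !is.finite(med)
  if (any(dead))
    stop("channel(s) with no observed intensities: ",
         paste(design$labels[dead], collapse = ", "))
  ref <- stats::median(med)
  for (i in seq_along(rc)) psms[[rc[i]]] <- psms[[rc[i]]] * (ref / med[i])
  psms
}

#' Average relative error of a ratio vector
#'
#' ARE compares an observed ratio vector against the theoretical ratios of
#' the channel design: \eqn{ARE = \frac{1}{n}\sum_i |x_i - y_i| / y_i}, the
#' mean relative deviation over the `n` predefined ratios. An ARE of 0 means
#' perfect agreement; 0.1 means the observed ratios deviate from the design
#' values by 10% on average.
#'
#' @param observed Numeric vector of observed ratios (or a matrix with one
#'   row per PSM).
#' @param theoretical Numeric vector of theoretical ratios, all positive.
#' @return A nonnegative scalar (or one value per row of `observed`).
#' @examples
#' psm_are(c(1.2, 0.8, 1.0, 1.0, 1.0), rep(1, 5))  # 0.08
#' @export
psm_are <- function(observed, theoretical) {
  if (any(!is.na(theoretical) & theoretical <= 0))
    stop("theoretical ratios must be positive")
  if (is.matrix(observed)) {
    if (ncol(observed) != length(theoretical))
      stop("observed has ", ncol(observed), " ratios but theoretical has ",
           length(theoretical))
    return(rowMeans(abs(sweep(observed, 2L, theoretical)) /
                      rep(theoretical, each = nrow(observed))))
  }
  if (length(observed) != length(theoretical))
    stop("observed and theoretical ratio vectors differ in length")
  mean(abs(observed - theoretical) / theoretical)
}

#' Quantitation eligibility of a PSM
#'
#' A PSM enters quantitation evaluation only if its peptide is not shared
#' between proteins and it has no missing reporter ion.
#'
#' @inheritParams normalize_reporters
#' @return Logical vector, one value per PSM.
#' @export
eligible_for_eval <- function(psms, design) {
  complete <- stats::complete.cases(reporter_matrix(psms, design))
  !psms$is_shared & complete
}

#' Area under the coverage-versus-ARE curve
#'
#' The coverage curve plots, against an ARE threshold `t`, the fraction of
#' PSMs whose ARE is at most `t` (the empirical CDF of the ARE values). Its
#' area over `t` in `[0, max_are]`, divided by `max_are`, summarizes
#' quantitation accuracy in `[0, 1]`: 1 when every PSM has ARE 0, larger
#' values meaning more PSMs quantified accurately. The step-function CDF is
#' integrated exactly.
#'
#' @param ares Numeric vector of nonnegative ARE values.
#' @param max_are Upper integration limit (default 1).
#' @return The normalized area, in `[0, 1]`.
#' @export
coverage_auc <- function(ares, max_are = 1) {
  ares <- ares[!is.na(ares)]
  if (!length(ares)) stop("coverage_auc needs at least one ARE value")
  if (max_are <= 0) stop("max_are must be positive")
  mean(max_are - pmin(ares, max_are)) / max_are
}

#' Protein quantitation by summed reporter intensity (SumPsmIntensity)
#'
#' For every protein, sums each channel's normalized reporter intensity over
#' all eligible PSMs assigned to it (primary accession; see
#' [eligible_for_eval()]), forms the channel ratios from the summed
#' intensities, and scores the protein's ARE against the design's theoretical
#' ratios. Proteins with no eligible PSM are omitted.
#'
#' @inheritParams normalize_reporters
#' @return A `data.frame` with one row per protein: `accession`, one
#'   `sum_<label>` column per channel, one `ratio_<label>` column per
#'   numerator channel, `are`, and `n_psms_used`.
#' @export
protein_quant_sum <- function(psms, design) {
  keep <- eligible_for_eval(psms, design)
  psms <- psms[keep, , drop = FALSE]
  if (!nrow(psms))
    return(data.frame(accession = character(), are = numeric(),
                      n_psms_used = integer(), stringsAsFactors = FALSE))
  m <- reporter_matrix(psms, design)
  acc <- sort(unique(psms$protein))
  sums <- t(vapply(acc, function(a)
    colSums(m[psms$protein == a, , drop = FALSE]), numeric(ncol(m))))
  ratios <- sums[, -design$denominator, drop = FALSE] /
    sums[, design$denominator]
  out <- data.frame(accession = acc, stringsAsFactors = FALSE)
  for (i in seq_along(design$labels))
    out[[paste0("sum_", design$labels[i])]] <- sums[, i]
  nl <- numerator_labels(design)
  for (i in seq_along(nl)) out[[paste0("ratio_", nl[i])]] <- ratios[, i]
  out$are <- psm_are(ratios, design$theoretical_ratios)
  out$n_psms_used <- as.integer(table(psms$protein)[acc])
  rownames(out) <- NULL
  out
}

#' Label the PSMs with the largest quantitation errors
#'
#' Marks the top `fraction` of PSMs by ARE (the "PSMs with larger
#' quantitation errors" used to derive filter thresholds): the
#' `ceiling(fraction * N)` keys with the largest ARE. Ties at the cutoff are
#' broken deterministically by ascending spectrum key.
#'
#' @param keys Character vector of spectrum keys.
#' @param ares Numeric vector of ARE values aligned with `keys`.
#' @param fraction Fraction of PSMs to label (default 0.25).
#' @return Character vector of the labeled keys.
#' @export
label_large_error <- function(keys, ares, fraction = 0.25) {
  if (!length(keys)) stop("no PSMs to label")
  if (length(keys) != length(ares)) stop("keys and ares differ in length")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  k <- ceiling(fraction * length(keys))
  ord <- order(-ares, keys)
  keys[ord][seq_len(k)]
}
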