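# Spectral features used by the feature-based PSM filter (FPF).
#
# Ten general features are computed for every PSM: charge state, precursor
# mass, peptide length, number of PTMs, PTM ratio (PTMs / length), absolute
# mass difference, average normalized reporter intensity, PeptideProphet
# F-value, and the two ratio-distance features IProtDist and IPepDist.
# Six more are available only for PSMs carrying spectral-library search
# scores. A feature that cannot be computed (missing reporter ion, no
# library scores) is NA; the filter bypasses conditions on NA features.

#' Per-PSM reporter-ion ratios
#'
#' Computes, for every PSM, the vector of `n = channels - 1` reporter ratios:
#' each non-denominator channel's intensity divided by the denominator
#' channel's intensity, in channel order. A PSM with any missing reporter ion
#' (or a zero denominator) gets an all-`NA` ratio vector — ratios are either
#' complete or absent, matching the filter's bypass rule.
#'
#' @param psms A PSM table with (normalized) reporter columns.
#' @param design A [channel_design()].
#' @return A numeric matrix, one row per PSM, one column per predefined
#'   ratio, with the numerator channel labels as column names.
#' @export
psm_ratios <- function(psms, design) {
  m <- reporter_matrix(psms, design)
  den <- m[, design$denominator]
  num <- m[, -design$denominator, drop = FALSE]
  r <- num / den
  bad <- !stats::complete.cases(m) | is.na(den) | den == 0
  r[bad, ] <- NA_real_
  colnames(r) <- numerator_labels(design)
  r
}

#' Average reporter-ion intensity
#'
#' Arithmetic mean of a PSM's normalized reporter intensities over all
#' channels; `NA` when any channel is missing, so that the filter's
#' low-intensity condition is bypassed for PSMs with missing reporter ions.
#'
#' @inheritParams psm_ratios
#' @return Numeric vector, one value per PSM.
#' @export
avg_reporter_intensity <- function(psms, design) {
  m <- reporter_matrix(psms, design)
  out <- rowMeans(m)          # NA whenever any channel is NA
  unname(out)
}

#' Intra-protein and intra-peptide ratio distance
#'
#' `iprotdist()` measures how far one PSM's ratio vector lies from the other
#' PSMs of the same protein:
#' \deqn{IProtDist_j = \sqrt{\sum_{i=1}^{n}
#'   \left(\frac{R_i^j - AvgRest_i}{Avg_i}\right)^2}}
#' where \eqn{R_i^j} is the i-th ratio of PSM j, \eqn{AvgRest_i} the mean of
#' ratio i over all peer PSMs except j, and \eqn{Avg_i} the mean over all
#' peers including j. It is 0 when the PSM is the only one in the peer set.
#'
#' `ipepdist()` applies the same formula with peers restricted to PSMs of the
#' same peptide sequence. Single-hit peptides (one PSM each) have no peers of
#' their own, so all single-hit peptides of a protein are merged into one
#' pseudo-peptide and the distance is computed within that merged set;
#' a PSM alone in its pseudo-peptide scores 0.
#'
#' Both functions operate within one protein: `ratios` holds the complete
#' ratio vectors of that protein's PSMs (rows), `target` selects the PSM
#' being scored. If any peer-set mean \eqn{Avg_i} is 0 the distance is
#' undefined and `NA` is returned with a warning.
#'
#' @param ratios Numeric matrix of complete ratio vectors (one row per PSM of
#'   one protein, one column per predefined ratio).
#' @param target Row index of the PSM to score.
#' @param peptides For `ipepdist()`, character vector of peptide sequences
#'   aligned with the rows of `ratios`.
#' @return A single nonnegative distance, or `NA` if undefined.
#' @examples
#' r <- matrix(c(1, 2), ncol = 1)
#' iprotdist(r, 1)  # |1 - 2| / 1.5
#' @export
iprotdist <- function(ratios, target) {
  ratio_distance(ratios, target)
}

#' @rdname iprotdist
#' @export
ipepdist <- function(ratios, peptides, target) {
  if (length(peptides) != nrow(ratios))
    stop("peptides must align with the rows of ratios")
  hits <- table(peptides)
  if (hits[[peptides[target]]] >= 2L) {
    peers <- which(peptides == peptides[target])
  } else {
    singles <- names(hits)[hits == 1L]
    peers <- which(peptides %in% singles)  # the merged pseudo-peptide
  }
  ratio_distance(ratios[peers, , drop = FALSE], match(target, peers))
}

# The shared distance kernel. `ratios`: peer matrix including the target row.
ratio_distance <- function(ratios, target) {
  k <- nrow(ratios)
  if (is.na(target) || target < 1L || target > k)
    stop("target row out of range")
  if (k == 1L) return(0)
  avg <- colMeans(ratios)
  if (any(avg == 0)) {
    warning("ratio distance undefined: a peer-set mean ratio is 0")
    return(NA_real_)
  }
  avg_rest <- (colSums(ratios) - ratios[target, ]) / (k - 1)
  sqrt(sum(((ratios[target, ] - avg_rest) / avg)^2))
}

#' Count post-translational modifications
#'
#' Number of modification entries on each PSM, excluding isobaric label tags
#' (TMT/iTRAQ reagent masses), which sit on essentially every labeled peptide
#' and carry no information about the identification. Set
#' `include_labels = TRUE` to count label tags as well.
#'
#' @param psms A PSM table.
#' @param include_labels Count label modifications too (default `FALSE`).
#' @return Integer vector of PTM counts.
#' @export
count_ptms <- function(psms, include_labels = FALSE) {
  vapply(psms$modifications, function(m) {
    if (is.null(m) || nrow(m) == 0L) return(0L)
    if (include_labels) nrow(m) else sum(!m$is_label)
  }, integer(1))
}

#' Compute the full FPF feature table
#'
#' Builds one row of spectral features per PSM: charge, precursor mass,
#' peptide length, PTM count and ratio, absolute mass difference, average
#' normalized reporter intensity, F-value, the intra-protein and
#' intra-peptide ratio distances, and the six spectral-library score
#' features. Distances are computed within each PSM's primary protein
#' accession, using only PSMs with complete reporter ratios as peers; PSMs
#' with missing reporter ions get `NA` for average intensity and both
#' distances (bypass state), and PSMs without library scores get `NA` for the
#' six `sl_*` features.
#'
#' @inheritParams psm_ratios
#' @param include_labels Passed to [count_ptms()].
#' @return A `data.frame` keyed by `spectrum_key` with one column per
#'   feature.
#' @export
featurize <- function(psms, design, include_labels = FALSE) {
  validate_psm_table(psms, design)
  keys <- psm_keys(psms)
  if (anyDuplicated(keys))
    stop("duplicate spectrum keys in PSM table")
  n_ptm <- count_ptms(psms, include_labels)
  len <- nchar(psms$peptide)
  feats <- data.frame(
    spectrum_key = keys,
    charge = psms$assumed_charge,
    precursor_mass_da = psms$precursor_neutral_mass_da,
    peptide_length = len,
    n_ptm = n_ptm,
    ptm_ratio = n_ptm / len,
    abs_mass_diff_da = abs(psms$mass_diff_da),
    avg_reporter_intensity = avg_reporter_intensity(psms, design),
    f_value = psms$f_value,
    iprotdist = NA_real_,
    ipepdist = NA_real_,
    stringsAsFactors = FALSE
  )
  for (cn in sl_score_cols) feats[[cn]] <- psms[[cn]]

  ratios <- psm_ratios(psms, design)
  complete <- stats::complete.cases(ratios)
  for (idx in split(which(complete), psms$protein[complete])) {
    r <- ratios[idx, , drop = FALSE]
    pep <- psms$peptide[idx]
    for (j in seq_along(idx)) {
      feats$iprotdist[idx[j]] <- iprotdist(r, j)
      feats$ipepdist[idx[j]] <- ipepdist(r, pep, j)
    }
  }
  rownames(feats) <- NULL
  feats
}
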