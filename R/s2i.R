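# Precursor signal-to-interference (S2I): the fraction of MS1 signal inside
# the isolation window that belongs to the targeted precursor and its
# isotopic cluster. Low S2I flags co-isolation interference that distorts
# reporter-ion ratios; the library-construction path drops PSMs below 0.7.

#' Bundle the MS1 context of one isolation event
#'
#' @param precursor_mz Selected precursor m/z (Th).
#' @param charge Precursor charge state (positive integer).
#' @param peaks Two-column numeric matrix (`mz`, `intensity`) of the MS1
#'   scan's peaks, or a `data.frame` with those columns.
#' @param isolation_center_mz Center of the isolation window (defaults to
#'   `precursor_mz`).
#' @param isolation_lower_offset,isolation_upper_offset Window half-widths
#'   below/above the center, in Th (default 0.85, a common quadrupole
#'   setting, used when the raw file lacks isolation metadata).
#' @return An object of class `ms1_context`.
#' @export
ms1_context <- function(precursor_mz, charge, peaks,
                        isolation_center_mz = precursor_mz,
                        isolation_lower_offset = 0.85,
                        isolation_upper_offset = 0.85) {
  if (is.data.frame(peaks)) peaks <- cbind(peaks$mz, peaks$intensity)
  peaks <- matrix(as.numeric(peaks), ncol = 2L,
                  dimnames = list(NULL, c("mz", "intensity")))
  if (nrow(peaks) > 1L && is.unsorted(peaks[, "mz"]))
    peaks <- peaks[order(peaks[, "mz"]), , drop = FALSE]
  if (isolation_lower_offset <= 0 || isolation_upper_offset <= 0)
    stop("isolation window offsets must be positive")
  structure(list(precursor_mz = precursor_mz, charge = as.integer(charge),
                 isolation_center_mz = isolation_center_mz,
                 isolation_lower_offset = isolation_lower_offset,
                 isolation_upper_offset = isolation_upper_offset,
                 peaks = peaks),
            class = "ms1_context")
}

#' Compute precursor signal-to-interference
#'
#' S2I = (summed intensity of peaks matching the precursor and its isotopic
#' cluster) / (summed intensity of all peaks inside the isolation window).
#' Isotope peaks are sought at `precursor_mz + k * spacing / charge` for
#' `k = 0..n_isotopes`, matched within `ppm_tol`, and only counted when they
#' fall inside the window. An empty window yields 0.
#'
#' @param ctx An [ms1_context()].
#' @param ppm_tol Peak-matching tolerance in parts per million (default 10).
#' @param n_isotopes Number of isotope peaks beyond the monoisotopic one
#'   (default 4).
#' @param isotope_spacing Neutron mass spacing in Da (default 1.00335).
#' @return S2I in `[0, 1]`.
#' @export
compute_s2i <- function(ctx, ppm_tol = 10, n_isotopes = 4,
                        isotope_spacing = 1.00335) {
  if (ctx$charge < 1L) stop("precursor charge must be >= 1")
  lo <- ctx$isolation_center_mz - ctx$isolation_lower_offset
  hi <- ctx$isolation_center_mz + ctx$isolation_upper_offset
  mz <- ctx$peaks[, "mz"]
  inten <- ctx$peaks[, "intensity"]
  inwin <- mz >= lo & mz <= hi
  total <- sum(inten[inwin])
  if (total == 0) return(0)
  targets <- ctx$precursor_mz + (0:n_isotopes) * isotope_spacing / ctx$charge
  is_signal <- rep(FALSE, length(mz))
  for (t in targets)
    is_signal <- is_signal | abs(mz - t) <= t * ppm_tol * 1e-6
  sum(inten[inwin & is_signal]) / total
}

#' Apply the S2I purity filter
#'
#' Retains PSMs whose precursor S2I is at least `threshold` (default 0.7;
#' PSMs with S2I strictly below it are removed). PSMs without an MS1 context
#' cannot be scored and are retained with a warning.
#'
#' @param psms A PSM table.
#' @param contexts Named list of [ms1_context()] objects keyed by
#'   [spectrum_key()].
#' @param threshold Minimum S2I to retain (default 0.7).
#' @param ... Passed to [compute_s2i()].
#' @return A list with PSM tables `retained` and `removed`, and `s2i`, the
#'   per-PSM S2I vector (`NA` where no context was available).
#' @export
s2i_filter <- function(psms, contexts, threshold = 0.7, ...) {
  keys <- psm_keys(psms)
  s2i <- vapply(keys, function(k) {
    ctx <- contexts[[k]]
    if (is.null(ctx)) NA_real_ else compute_s2i(ctx, ...)
  }, numeric(1))
  if (anyNA(s2i))
    warning(sum(is.na(s2i)), " PSM(s) without MS1 context retained unscored")
  keep <- is.na(s2i) | s2i >= threshold
  list(retained = psms[keep, , drop = FALSE],
       removed = psms[!keep, , drop = FALSE],
       s2i = s2i)
}

#' Extract MS1 contexts from an mzML file
#'
#' For each PSM, locates its MS2 scan in the mzML file, reads the precursor
#' m/z and isolation-window metadata, and pairs them with the peak list of
#' the nearest preceding MS1 scan. Requires the `mzR` package.
#'
#' @param mzml_path Path to an mzML file containing MS1 and MS2 scans.
#' @param psms A PSM table whose `scan_number`s refer to this file.
#' @param default_half_width Isolation half-width (Th) used when the file
#'   carries no isolation-window metadata (default 0.85).
#' @return Named list of [ms1_context()] keyed by [spectrum_key()]; PSMs
#'   whose scan or preceding MS1 scan is absent are skipped with a warning.
#' @export
read_ms1_contexts <- function(mzml_path, psms, default_half_width = 0.85) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("read_ms1_contexts() requires the mzR package")
  f <- mzR::openMSfile(mzml_path)
  on.exit(mzR::close(f))
  h <- mzR::header(f)
  contexts <- list()
  skipped <- 0L
  for (i in seq_len(nrow(psms))) {
    row <- which(h$acquisitionNum == psms$scan_number[i] & h$msLevel == 2L)
    ms1 <- which(h$msLevel == 1L & h$acquisitionNum < psms$scan_number[i])
    if (length(row) != 1L || !length(ms1)) { skipped <- skipped + 1L; next }
    ms1 <- ms1[which.max(h$acquisitionNum[ms1])]
    pk <- mzR::peaks(f, ms1)
    colnames(pk) <- c("mz", "intensity")
    center <- h$isolationWindowTargetMZ[row]
    if (is.na(center)) center <- h$precursorMZ[row]
    lo <- h$isolationWindowLowerOffset[row]
    hi <- h$isolationWindowUpperOffset[row]
    if (is.na(lo)) lo <- default_half_width
    if (is.na(hi)) hi <- default_half_width
    charge <- psms$assumed_charge[i]
    contexts[[spectrum_key(psms$run_basename[i], psms$scan_number[i],
                           charge)]] <-
      ms1_context(h$precursorMZ[row], charge, pk,
                  isolation_center_mz = center,
                  isolation_lower_offset = lo, isolation_upper_offset = hi)
  }
  if (skipped)
    warning(skipped, " PSM(s) had no matching MS2 or preceding MS1 scan")
  contexts
}
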