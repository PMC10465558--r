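#' @name psm-table
#' @title The PSM table
#'
#' @description
#' All functions in this package exchange peptide-spectrum matches (PSMs) as a
#' plain `data.frame` with one row per PSM. Columns:
#'
#' * `run_basename`, `scan_number`, `assumed_charge` — the spectrum identity;
#'   `spectrum_key` is their canonical string form (see [spectrum_key()]).
#' * `peptide` — uppercase stripped amino-acid sequence.
#' * `protein` — primary (first-listed) protein accession; `all_proteins` —
#'   every accession, `";"`-separated; `is_shared` — `TRUE` when the peptide
#'   maps to more than one distinct accession.
#' * `precursor_neutral_mass_da`, `calc_neutral_pep_mass_da`, `mass_diff_da` —
#'   observed neutral mass, theoretical peptide mass, and their difference
#'   (observed minus theoretical), all in Da.
#' * `iprophet_probability` — iProphet posterior; `f_value` — PeptideProphet
#'   discriminant score (`NA` when not reported).
#' * `modifications` — list column; each element a `data.frame` with
#'   `position` (1-based residue index, 0 = N terminus), `mass_delta_da`,
#'   `is_label` (isobaric label tags vs. biological/other modifications).
#' * `sl_precursor_mz_diff_abs`, `sl_dot`, `sl_delta`, `sl_n_hits`,
#'   `sl_hit_mean`, `sl_hit_std` — spectral-library (SpectraST) search scores;
#'   all `NA` for PSMs identified only by sequence-database engines.
#' * `reporter_<label>` — one column per channel of the governing
#'   [channel_design()], holding normalized or raw reporter-ion intensities;
#'   `NA` marks a missing reporter ion (absent or zero-intensity reporter).
NULL

#' Canonical spectrum key
#'
#' Builds the string key `"<run>.<scan>.<charge>"` that identifies one
#' acquired spectrum (at one assumed charge state) across the package: set
#' comparison of search results, filter decisions and truth tables are all
#' keyed on it. The charge is part of the key because TPP treats the same scan
#' searched at different charge states as distinct queries.
#'
#' @param run_basename Character vector of run base names.
#' @param scan_number Integer vector of scan numbers.
#' @param assumed_charge Integer vector of charge states.
#' @return Character vector of keys.
#' @examples
#' spectrum_key("run01", 2314, 2)
#' @export
spectrum_key <- function(run_basename, scan_number, assumed_charge) {
  paste(run_basename, as.integer(scan_number), as.integer(assumed_charge),
        sep = ".")
}

# Mass deltas (Da) of common isobaric label reagents; a modification whose
# delta is within `tol` of one of these is flagged is_label.
.label_deltas <- c(
  tmt6 = 229.162932, tmtpro = 304.207146,
  itraq4 = 144.102063, itraq8 = 304.205360
)

is_label_delta <- function(delta, tol = 0.01) {
  vapply(delta, function(d) any(abs(d - .label_deltas) <= tol), logical(1))
}

# Monoisotopic residue masses, used to convert between pepXML's absolute
# modified-residue masses and mass deltas.
.residue_mass <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
.water_mass <- 18.010565

peptide_neutral_mass <- function(peptide, mod_delta_total = 0) {
  aa <- strsplit(peptide, "")[[1]]
  sum(.residue_mass[aa]) + .water_mass + mod_delta_total
}

empty_modifications <- function() {
  data.frame(position = integer(), mass_delta_da = numeric(),
             is_label = logical())
}

# Validate the shape of a PSM table against a design; returns it invisibly.
validate_psm_table <- function(psms, design = NULL) {
  needed <- c("run_basename", "scan_number", "assumed_charge", "peptide",
              "protein", "all_proteins", "is_shared",
              "precursor_neutral_mass_da", "calc_neutral_pep_mass_da",
              "mass_diff_da", "iprophet_probability", "f_value",
              "modifications", sl_score_cols)
  miss <- setdiff(needed, names(psms))
  if (length(miss))
    stop("PSM table is missing column(s): ", paste(miss, collapse = ", "))
  if (!is.null(design)) {
    rc <- reporter_cols(design)
    miss <- setdiff(rc, names(psms))
    if (length(miss))
      stop("PSM table lacks reporter column(s) for the channel design: ",
           paste(miss, collapse = ", "))
  }
  invisible(psms)
}

sl_score_cols <- c("sl_precursor_mz_diff_abs", "sl_dot", "sl_delta",
                   "sl_n_hits", "sl_hit_mean", "sl_hit_std")

empty_psm_table <- function(design) {
  psms <- data.frame(
    run_basename = character(), scan_number = integer(),
    assumed_charge = integer(), peptide = character(), protein = character(),
    all_proteins = character(), is_shared = logical(),
    precursor_neutral_mass_da = numeric(), calc_neutral_pep_mass_da = numeric(),
    mass_diff_da = numeric(), iprophet_probability = numeric(),
    f_value = numeric(), stringsAsFactors = FALSE
  )
  psms$modifications <- list()
  for (cn in sl_score_cols) psms[[cn]] <- numeric()
  for (cn in reporter_cols(design)) psms[[cn]] <- numeric()
  psms
}

psm_keys <- function(psms) {
  spectrum_key(psms$run_basename, psms$scan_number, psms$assumed_charge)
}

# Reporter intensity matrix (rows = PSMs, columns = channels in design order).
reporter_matrix <- function(psms, design) {
  m <- as.matrix(psms[, reporter_cols(design), drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- list(NULL, design$labels)
  m
}

serialize_mods <- function(mods) {
  vapply(mods, function(m) {
    if (is.null(m) || nrow(m) == 0L) return("")
    paste(sprintf("%d:%.*g:%d", m$position, 10, m$mass_delta_da,
                  as.integer(m$is_label)), collapse = ";")
  }, character(1))
}

parse_mods <- function(s) {
  lapply(s, function(x) {
    if (is.na(x) || !nzchar(x)) return(empty_modifications())
    parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    data.frame(
      position = as.integer(vapply(parts, `[`, "", 1L)),
      mass_delta_da = as.numeric(vapply(parts, `[`, "", 2L)),
      is_label = as.logical(as.integer(vapply(parts, `[`, "", 3L)))
    )
  })
}

#' Read and write the canonical PSM table as TSV
#'
#' The TSV holds one row per PSM with the columns documented in
#' [psm-table]; modifications are packed into a single
#' `modifications` column as `position:mass_delta:is_label` triplets joined by
#' `";"`, and missing values (including missing reporter ions) are empty
#' cells. The round trip `read_psm_table(write_psm_table(x))` is lossless.
#'
#' @param psms A PSM table.
#' @param path File path.
#' @return `read_psm_table()` returns a PSM table; `write_psm_table()`
#'   returns `path` invisibly.
#' @export
write_psm_table <- function(psms, path) {
  out <- psms
  out$modifications <- serialize_mods(psms$modifications)
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) {
    y <- sprintf("%.17g", x)
    y[is.na(x)] <- NA_character_
    y
  })
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_psm_table
#' @export
read_psm_table <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", na.strings = "",
                           colClasses = "character", check.names = FALSE)
  known_chr <- c("run_basename", "peptide", "protein", "all_proteins",
                 "modifications")
  known_int <- c("scan_number", "assumed_charge")
  known_lgl <- "is_shared"
  unknown <- setdiff(names(raw), c(known_chr, known_int, known_lgl,
                                   "precursor_neutral_mass_da",
                                   "calc_neutral_pep_mass_da", "mass_diff_da",
                                   "iprophet_probability", "f_value",
                                   sl_score_cols))
  unknown <- unknown[!grepl("^reporter_", unknown)]
  if (length(unknown))
    stop("unknown column(s) in PSM table: ", paste(unknown, collapse = ", "))
  psms <- raw
  for (cn in intersect(known_int, names(psms)))
    psms[[cn]] <- as.integer(psms[[cn]])
  for (cn in intersect(known_lgl, names(psms)))
    psms[[cn]] <- as.logical(psms[[cn]])
  numcols <- setdiff(names(psms), c(known_chr, known_int, known_lgl))
  for (cn in numcols) psms[[cn]] <- as.numeric(psms[[cn]])
  psms$modifications <- parse_mods(raw$modifications)
  keys <- psm_keys(psms)
  if (anyDuplicated(keys))
    stop("duplicate spectrum keys in PSM table: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  validate_psm_table(psms)
  psms
}
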