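# pepXML (TPP iProphet dialect) reading and writing, built on xml2.
#
# Only the rank-1 search hit of each spectrum_query is read: downstream
# quantitation uses a single identification per spectrum. Reporter-ion
# intensities are taken from Libra-style <intensity> elements inside the
# hit's libra analysis_result when present; a zero or absent intensity is an
# explicit missing value, never a silent 0.

strip_ns <- function(doc) {
  xml2::xml_ns_strip(doc)
  doc
}

# "<base>.<scan>.<scan>.<charge>" -> base name (strip the last 3 dot fields)
spectrum_attr_basename <- function(spectrum) {
  sub("\\.[0-9]+\\.[0-9]+\\.[0-9]+$", "", spectrum)
}

xattr_num <- function(node, attr) {
  v <- xml2::xml_attr(node, attr)
  ifelse(is.na(v), NA_real_, suppressWarnings(as.numeric(v)))
}

.spectrast_score_map <- c(
  precursor_mz_diff = "sl_precursor_mz_diff_abs",
  dot = "sl_dot",
  delta = "sl_delta",
  hits_num = "sl_n_hits",
  hits_mean = "sl_hit_mean",
  hits_stdev = "sl_hit_std"
)

#' Read PSMs from an iProphet-dialect pepXML file
#'
#' Parses every `spectrum_query` element and returns the rank-1 search hit of
#' each as one row of a PSM table (see [psm-table]). The PeptideProphet
#' discriminant score is taken from the `fval` search score when present, and
#' SpectraST scores (`dot`, `delta`, `precursor_mz_diff`, `hits_num`,
#' `hits_mean`, `hits_stdev`) are populated only for hits that carry them.
#' Reporter intensities come from Libra-style `<intensity>` elements; a
#' channel whose element is absent or has `absolute="0"` is recorded as
#' missing (`NA`).
#'
#' @param path Path to a pepXML file.
#' @param design A [channel_design()]; the number of distinct Libra channels
#'   found in the file must not exceed the design's channel count.
#' @return A PSM table with one reporter column per design channel.
#' @export
read_pepxml <- function(path, design) {
  if (!file.exists(path)) stop("pepXML file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed pepXML in ", path, ": ", conditionMessage(e)))
  strip_ns(doc)
  queries <- xml2::xml_find_all(doc, ".//spectrum_query")
  rc <- reporter_cols(design)
  rows <- lapply(queries, function(q) {
    spectrum <- xml2::xml_attr(q, "spectrum")
    hit <- xml2::xml_find_first(q, "./search_result/search_hit[@hit_rank='1']")
    if (inherits(hit, "xml_missing"))
      hit <- xml2::xml_find_first(q, "./search_result/search_hit")
    if (inherits(hit, "xml_missing")) return(NULL)
    alt <- xml2::xml_attr(
      xml2::xml_find_all(hit, "./alternative_protein"), "protein")
    prots <- unique(c(xml2::xml_attr(hit, "protein"), alt))
    scores <- xml2::xml_find_all(hit, "./search_score")
    sname <- xml2::xml_attr(scores, "name")
    sval <- suppressWarnings(as.numeric(xml2::xml_attr(scores, "value")))
    names(sval) <- sname

    peptide <- xml2::xml_attr(hit, "peptide")
    mods <- empty_modifications()
    minfo <- xml2::xml_find_first(hit, "./modification_info")
    if (!inherits(minfo, "xml_missing")) {
      ntm <- xattr_num(minfo, "mod_nterm_mass")
      if (!is.na(ntm)) {
        d <- ntm - 1.007825  # nterm H
        mods <- rbind(mods, data.frame(position = 0L, mass_delta_da = d,
                                       is_label = is_label_delta(d)))
      }
      for (ma in xml2::xml_find_all(minfo, "./mod_aminoacid_mass")) {
        pos <- as.integer(xml2::xml_attr(ma, "position"))
        total <- xattr_num(ma, "mass")
        aa <- substr(peptide, pos, pos)
        d <- total - unname(.residue_mass[aa])
        mods <- rbind(mods, data.frame(position = pos, mass_delta_da = d,
                                       is_label = is_label_delta(d)))
      }
    }

    prob <- xattr_num(xml2::xml_find_first(
      hit, "./analysis_result[@analysis='interprophet']/interprophet_result"),
      "probability")
    if (is.na(prob))
      prob <- xattr_num(xml2::xml_find_first(
        hit,
        "./analysis_result[@analysis='peptideprophet']/peptideprophet_result"),
        "probability")

    intens <- xml2::xml_find_all(
      hit, "./analysis_result[@analysis='libra']/libra_result/intensity")
    rep_vals <- rep(NA_real_, length(rc))
    if (length(intens)) {
      ch <- as.integer(xml2::xml_attr(intens, "channel"))
      if (any(ch > length(rc)))
        stop("pepXML reports Libra channel ", max(ch),
             " but the channel design has only ", length(rc), " channels")
      ab <- suppressWarnings(as.numeric(xml2::xml_attr(intens, "absolute")))
      ab[!is.na(ab) & ab == 0] <- NA_real_
      rep_vals[ch] <- ab
    }

    precursor <- xattr_num(q, "precursor_neutral_mass")
    calc <- xattr_num(hit, "calc_neutral_pep_mass")
    mdiff <- xattr_num(hit, "massdiff")
    if (is.na(mdiff)) mdiff <- precursor - calc
    row <- data.frame(
      run_basename = spectrum_attr_basename(spectrum),
      scan_number = as.integer(xml2::xml_attr(q, "start_scan")),
      assumed_charge = as.integer(xml2::xml_attr(q, "assumed_charge")),
      peptide = peptide,
      protein = prots[1],
      all_proteins = paste(prots, collapse = ";"),
      is_shared = length(prots) > 1L,
      precursor_neutral_mass_da = precursor,
      calc_neutral_pep_mass_da = calc,
      mass_diff_da = mdiff,
      iprophet_probability = prob,
      f_value = if ("fval" %in% sname) unname(sval["fval"]) else NA_real_,
      stringsAsFactors = FALSE
    )
    row$modifications <- I(list(mods))
    has_sl <- any(names(.spectrast_score_map) %in% sname)
    for (nm in names(.spectrast_score_map)) {
      v <- if (has_sl && nm %in% sname) unname(sval[nm]) else NA_real_
      if (nm == "precursor_mz_diff" && !is.na(v)) v <- abs(v)
      row[[.spectrast_score_map[[nm]]]] <- v
    }
    for (i in seq_along(rc)) row[[rc[i]]] <- rep_vals[i]
    row
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_psm_table(design))
  psms <- do.call(rbind, rows)
  rownames(psms) <- NULL
  psms$modifications <- lapply(psms$modifications, identity)
  validate_psm_table(psms, design)
  psms
}

#' Remove spectrum queries from a pepXML file
#'
#' Writes a copy of `source` in which the `spectrum_query` elements whose
#' spectrum keys are in `removed` have been deleted. Everything else —
#' headers, analysis summaries, run summaries, unrelated queries — is
#' preserved, so the output stays compatible with downstream TPP tools
#' (ProteinProphet, Libra). Any pre-existing `analysis_summary` counts are
#' left verbatim rather than recomputed.
#'
#' @param source Path to the input pepXML.
#' @param removed Character vector of [spectrum_key()] strings to delete.
#' @param dest Output path.
#' @return The number of deleted `spectrum_query` elements (invisibly equal
#'   to `length(unique(removed))`).
#' @export
write_filtered_pepxml <- function(source, removed, dest) {
  doc <- tryCatch(xml2::read_xml(source), error = function(e)
    stop("malformed pepXML in ", source, ": ", conditionMessage(e)))
  strip_ns(doc)
  queries <- xml2::xml_find_all(doc, ".//spectrum_query")
  keys <- spectrum_key(
    spectrum_attr_basename(xml2::xml_attr(queries, "spectrum")),
    as.integer(xml2::xml_attr(queries, "start_scan")),
    as.integer(xml2::xml_attr(queries, "assumed_charge"))
  )
  removed <- unique(as.character(removed))
  missing <- setdiff(removed, keys)
  if (length(missing))
    stop("spectrum key(s) not present in ", source, ": ",
         paste(missing, collapse = ", "))
  drop <- which(keys %in% removed)
  for (i in drop) xml2::xml_remove(queries[[i]])
  xml2::write_xml(doc, dest)
  invisible(length(drop))
}
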