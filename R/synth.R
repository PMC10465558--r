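# Synthetic multi-channel PSM data sets with known ground truth.
#
# The generator emulates the structure of a two-proteome isobaric mixture
# benchmark: many proteins, several PSMs each, reporter intensities that
# follow the design's theoretical ratios up to multiplicative lognormal
# noise, and a controllable fraction of "bad" PSMs whose ratio noise is
# inflated. When feature coupling is on, bad PSMs preferentially have low
# intensity, long peptides and high charge, mimicking how quantitation
# error correlates with those spectral features in real data.

#' Configuration for the synthetic PSM generator
#'
#' Defaults model an equimolar TMT 6-plex experiment: 400 proteins averaging
#' 10 PSMs each (negative binomial, dispersion 5), lognormal base intensity
#' (median 50,000 counts, sdlog 1), 10% multiplicative ratio noise
#' (coefficient of variation) on ordinary PSMs, 25% of PSMs "bad" with 5x
#' that noise, 2% of PSMs missing one reporter channel, 5% shared peptides,
#' and half of the PSMs carrying spectral-library search scores.
#'
#' @param seed Integer RNG seed; the generator is fully reproducible from it.
#' @param n_proteins,psms_per_protein_mean,psms_per_protein_dispersion
#'   Protein count and the negative-binomial PSM count per protein
#'   (minimum 1).
#' @param design A [channel_design()] providing channels, denominator and
#'   theoretical ratios.
#' @param base_intensity_meanlog,base_intensity_sdlog Lognormal parameters
#'   of the per-PSM denominator-channel intensity.
#' @param ratio_noise_cv Coefficient of variation of the multiplicative
#'   lognormal noise applied per channel.
#' @param frac_bad Fraction of PSMs with inflated noise.
#' @param bad_error_multiplier Noise CV multiplier for bad PSMs (> 1).
#' @param frac_missing_reporter Fraction of PSMs with one missing channel.
#' @param frac_shared_peptides Fraction of PSMs whose peptide is shared with
#'   a second protein.
#' @param frac_sl Fraction of PSMs carrying spectral-library scores.
#' @param couple_intensity,couple_length,couple_charge When `TRUE` (default),
#'   bad PSMs are biased toward low base intensity, peptide length >= 25,
#'   and charge >= 5, respectively.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_proteins = 400L,
                         psms_per_protein_mean = 10,
                         psms_per_protein_dispersion = 5,
                         design = channel_design(
                           c("126", "127", "128", "129", "130", "131")),
                         base_intensity_meanlog = log(5e4),
                         base_intensity_sdlog = 1,
                         ratio_noise_cv = 0.1,
                         frac_bad = 0.25,
                         bad_error_multiplier = 5,
                         frac_missing_reporter = 0.02,
                         frac_shared_peptides = 0.05,
                         frac_sl = 0.5,
                         couple_intensity = TRUE,
                         couple_length = TRUE,
                         couple_charge = TRUE) {
  cfg <- as.list(environment())
  fracs <- c(frac_bad, frac_missing_reporter, frac_shared_peptides, frac_sl)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (bad_error_multiplier <= 1) stop("bad_error_multiplier must exceed 1")
  if (n_proteins < 1L) stop("need at least one protein")
  if (frac_shared_peptides > 0 && n_proteins < 2L)
    stop("shared peptides require at least two proteins")
  class(cfg) <- "synth_config"
  cfg
}

random_peptide <- function(length) {
  paste(sample(names(.residue_mass), length, replace = TRUE), collapse = "")
}

#' Generate a synthetic PSM data set with known ground truth
#'
#' Draws a full PSM table following a [synth_config()], plus a truth table
#' recording which PSMs were generated as "bad" (inflated ratio noise) and
#' the true ratio vector every PSM was generated from. Reporter intensities
#' are `base * theoretical_ratio * lognormal noise`, with the noise sdlog set
#' from the configured coefficient of variation
#' (`sdlog = sqrt(log(1 + cv^2))`); bad PSMs use `cv * bad_error_multiplier`.
#' All sampling comes from one RNG stream seeded by `config$seed`, so equal
#' seeds give identical output.
#'
#' @param config A [synth_config()].
#' @return A list with elements `psms` (PSM table), `truth` (`data.frame`
#'   with `spectrum_key`, `is_bad`, and one `true_ratio_<label>` column per
#'   numerator channel) and `design`.
#' @export
generate_psms <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  design <- config$design
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  counts <- pmax(1L, stats::rnbinom(config$n_proteins,
                                    mu = config$psms_per_protein_mean,
                                    size = config$psms_per_protein_dispersion))
  n <- sum(counts)
  protein <- rep(sprintf("PROT%04d", seq_len(config$n_proteins)), counts)
  is_bad <- stats::runif(n) < config$frac_bad

  # peptides: ~2/3 as many peptides as PSMs per protein, so some peptides
  # get several PSMs and others are single-hit
  peptide <- character(n)
  for (idx in split(seq_len(n), protein)) {
    k <- length(idx)
    npep <- max(1L, ceiling(k / 1.5))
    lens <- integer(npep)
    for (p in seq_len(npep)) {
      long <- FALSE
      # couple length to badness of the first PSM drawn for the peptide
      if (config$couple_length && is_bad[idx[((p - 1L) %% k) + 1L]])
        long <- stats::runif(1) < 0.6
      lens[p] <- if (long) sample(25:40, 1L) else sample(8:24, 1L)
    }
    peps <- vapply(lens, random_peptide, character(1))
    assign_to <- sample(rep(seq_len(npep), length.out = k))
    peptide[idx] <- peps[assign_to]
  }
  len <- nchar(peptide)

  charge <- sample(2:4, n, replace = TRUE, prob = c(0.5, 0.35, 0.15))
  if (config$couple_charge) {
    hi <- is_bad & stats::runif(n) < 0.3
    charge[hi] <- sample(5:6, sum(hi), replace = TRUE)
  }

  meanlog <- rep(config$base_intensity_meanlog, n)
  if (config$couple_intensity) meanlog[is_bad] <- meanlog[is_bad] - 2.2
  base <- stats::rlnorm(n, meanlog, config$base_intensity_sdlog)

  cv <- ifelse(is_bad, config$ratio_noise_cv * config$bad_error_multiplier,
               config$ratio_noise_cv)
  sdlog <- sqrt(log(1 + cv^2))
  k <- length(design$labels)
  expected <- numeric(k)
  expected[design$denominator] <- 1
  expected[-design$denominator] <- design$theoretical_ratios
  inten <- matrix(NA_real_, n, k)
  for (ch in seq_len(k)) {
    noise <- if (all(sdlog == 0)) rep(1, n) else
      stats::rlnorm(n, -sdlog^2 / 2, sdlog)
    inten[, ch] <- base * expected[ch] * noise
  }
  miss <- stats::runif(n) < config$frac_missing_reporter
  miss_ch <- sample.int(k, n, replace = TRUE)
  inten[cbind(which(miss), miss_ch[miss])] <- NA_real_

  shared <- stats::runif(n) < config$frac_shared_peptides
  other <- sprintf("PROT%04d", sample.int(config$n_proteins, n,
                                          replace = TRUE))
  # a shared peptide needs a second, distinct accession
  clash <- shared & other == protein
  while (any(clash)) {
    other[clash] <- sprintf("PROT%04d",
                            sample.int(config$n_proteins, sum(clash),
                                       replace = TRUE))
    clash <- shared & other == protein
  }

  has_sl <- stats::runif(n) < config$frac_sl
  mods <- lapply(seq_len(n), function(i) {
    m <- data.frame(position = 0L, mass_delta_da = .label_deltas[["tmt6"]],
                    is_label = TRUE)
    kpos <- which(strsplit(peptide[i], "")[[1]] == "K")
    if (length(kpos))
      m <- rbind(m, data.frame(position = kpos,
                               mass_delta_da = .label_deltas[["tmt6"]],
                               is_label = TRUE))
    if (stats::runif(1) < 0.15) {
      mpos <- which(strsplit(peptide[i], "")[[1]] == "M")
      if (length(mpos))
        m <- rbind(m, data.frame(position = mpos[1], mass_delta_da = 15.9949,
                                 is_label = FALSE))
    }
    m
  })
  calc_mass <- vapply(seq_len(n), function(i)
    peptide_neutral_mass(peptide[i], sum(mods[[i]]$mass_delta_da)),
    numeric(1))
  mass_diff <- stats::rnorm(n, 0, 0.003)
  run <- "synthrun"
  psms <- data.frame(
    run_basename = run,
    scan_number = seq_len(n) * 2L + 1L,
    assumed_charge = charge,
    peptide = peptide,
    protein = protein,
    all_proteins = ifelse(shared, paste(protein, other, sep = ";"), protein),
    is_shared = shared,
    precursor_neutral_mass_da = calc_mass + mass_diff,
    calc_neutral_pep_mass_da = calc_mass,
    mass_diff_da = mass_diff,
    iprophet_probability = stats::rbeta(n, 20, 1),
    f_value = round(stats::rnorm(n, 2.5, 1.2), 4),
    stringsAsFactors = FALSE
  )
  psms$modifications <- mods
  psms$sl_precursor_mz_diff_abs <- ifelse(has_sl,
                                          abs(stats::rnorm(n, 0, 0.01)),
                                          NA_real_)
  psms$sl_dot <- ifelse(has_sl, stats::rbeta(n, 8, 2), NA_real_)
  psms$sl_delta <- ifelse(has_sl, stats::runif(n, 0, 0.5), NA_real_)
  psms$sl_n_hits <- ifelse(has_sl, sample(1:10, n, replace = TRUE),
                           NA_real_)
  psms$sl_hit_mean <- ifelse(has_sl, stats::rbeta(n, 4, 4), NA_real_)
  psms$sl_hit_std <- ifelse(has_sl, stats::runif(n, 0, 0.2), NA_real_)
  rc <- reporter_cols(design)
  for (i in seq_len(k)) psms[[rc[i]]] <- inten[, i]

  truth <- data.frame(spectrum_key = psm_keys(psms), is_bad = is_bad,
                      stringsAsFactors = FALSE)
  nl <- numerator_labels(design)
  for (i in seq_along(nl))
    truth[[paste0("true_ratio_", nl[i])]] <- design$theoretical_ratios[i]
  list(psms = psms, truth = truth, design = design)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write a PSM table as an iProphet-dialect pepXML fixture
#'
#' Serializes a PSM table into a minimal but schema-conformant pepXML file:
#' one `msms_run_summary` per run, one `spectrum_query` per PSM with a
#' rank-1 `search_hit` carrying proteins, modifications, the `fval` search
#' score, SpectraST scores when present, the iProphet probability, and
#' Libra-style per-channel reporter intensities. [read_pepxml()] recovers
#' every field.
#'
#' @param psms A PSM table.
#' @param path Output path.
#' @param design A [channel_design()].
#' @return `path`, invisibly.
#' @export
write_pepxml <- function(psms, path, design) {
  validate_psm_table(psms, design)
  doc <- xml2::xml_new_root(
    "msms_pipeline_analysis",
    date = "2026-01-01T00:00:00", summary_xml = basename(path),
    xmlns = "http://regis-web.systemsbiology.net/pepXML"
  )
  asum <- xml2::xml_add_child(doc, "analysis_summary",
                              analysis = "interprophet",
                              time = "2026-01-01T00:00:00")
  xml2::xml_add_child(asum, "interprophet_summary", version = "fixture")
  fmt <- function(x) sprintf("%.9f", x)
  rc <- reporter_cols(design)
  rev_map <- stats::setNames(names(.spectrast_score_map),
                             .spectrast_score_map)
  for (run in unique(psms$run_basename)) {
    rs <- xml2::xml_add_child(doc, "msms_run_summary", base_name = run,
                              raw_data_type = "raw", raw_data = ".mzML")
    xml2::xml_add_child(rs, "search_summary", base_name = run,
                        search_engine = "Comet",
                        precursor_mass_type = "monoisotopic",
                        fragment_mass_type = "monoisotopic")
    sub <- psms[psms$run_basename == run, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      p <- sub[i, ]
      q <- xml2::xml_add_child(
        rs, "spectrum_query",
        spectrum = sprintf("%s.%05d.%05d.%d", run, p$scan_number,
                           p$scan_number, p$assumed_charge),
        start_scan = as.character(p$scan_number),
        end_scan = as.character(p$scan_number),
        precursor_neutral_mass = fmt(p$precursor_neutral_mass_da),
        assumed_charge = as.character(p$assumed_charge),
        index = as.character(i)
      )
      sr <- xml2::xml_add_child(q, "search_result")
      prots <- strsplit(p$all_proteins, ";", fixed = TRUE)[[1]]
      hit <- xml2::xml_add_child(
        sr, "search_hit", hit_rank = "1", peptide = p$peptide,
        protein = prots[1], num_tot_proteins = as.character(length(prots)),
        calc_neutral_pep_mass = fmt(p$calc_neutral_pep_mass_da),
        massdiff = fmt(p$mass_diff_da)
      )
      for (ap in prots[-1])
        xml2::xml_add_child(hit, "alternative_protein", protein = ap)
      mods <- p$modifications[[1]]
      if (!is.null(mods) && nrow(mods)) {
        minfo <- xml2::xml_add_child(hit, "modification_info")
        nt <- mods$position == 0L
        if (any(nt))
          xml2::xml_attr(minfo, "mod_nterm_mass") <-
            fmt(1.007825 + sum(mods$mass_delta_da[nt]))
        for (j in which(!nt)) {
          aa <- substr(p$peptide, mods$position[j], mods$position[j])
          xml2::xml_add_child(
            minfo, "mod_aminoacid_mass",
            position = as.character(mods$position[j]),
            mass = fmt(.residue_mass[[aa]] + mods$mass_delta_da[j])
          )
        }
      }
      if (!is.na(p$f_value))
        xml2::xml_add_child(hit, "search_score", name = "fval",
                            value = fmt(p$f_value))
      for (cn in sl_score_cols) {
        if (!is.na(p[[cn]]))
          xml2::xml_add_child(hit, "search_score", name = rev_map[[cn]],
                              value = fmt(p[[cn]]))
      }
      if (!is.na(p$iprophet_probability)) {
        ar <- xml2::xml_add_child(hit, "analysis_result",
                                  analysis = "interprophet")
        xml2::xml_add_child(ar, "interprophet_result",
                            probability = fmt(p$iprophet_probability))
      }
      vals <- unlist(p[rc])
      if (any(!is.na(vals))) {
        ar <- xml2::xml_add_child(hit, "analysis_result", analysis = "libra")
        lr <- xml2::xml_add_child(ar, "libra_result")
        for (ch in which(!is.na(vals)))
          xml2::xml_add_child(lr, "intensity", channel = as.character(ch),
                              target_mass = design$labels[ch],
                              absolute = fmt(vals[ch]), normalized = "0")
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
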