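# Shared fixture builders and independent oracles.

design3 <- channel_design(c("126", "127", "128"))
design6 <- channel_design(c("126", "127", "128", "129", "130", "131"))

# Build a hand-specified PSM table. `reporters` is an n x k matrix (NA =
# missing reporter ion); scalar arguments are recycled across rows.
toy_psms <- function(reporters, design, peptide = "PEPTIDEK",
                     protein = "P1", charge = 2L, is_shared = FALSE,
                     precursor_mass = 1500.2, calc_mass = 1500.2,
                     f_value = 2, sl_dot = NA_real_, run = "run01") {
  reporters <- matrix(reporters, ncol = length(design$labels))
  n <- nrow(reporters)
  psms <- data.frame(
    run_basename = rep_len(run, n),
    scan_number = seq_len(n),
    assumed_charge = as.integer(rep_len(charge, n)),
    peptide = rep_len(peptide, n),
    protein = rep_len(protein, n),
    all_proteins = rep_len(protein, n),
    is_shared = rep_len(is_shared, n),
    precursor_neutral_mass_da = rep_len(precursor_mass, n),
    calc_neutral_pep_mass_da = rep_len(calc_mass, n),
    mass_diff_da = rep_len(precursor_mass - calc_mass, n),
    iprophet_probability = 0.99,
    f_value = rep_len(f_value, n),
    stringsAsFactors = FALSE
  )
  psms$modifications <- replicate(n, data.frame(position = integer(),
                                                mass_delta_da = numeric(),
                                                is_label = logical()),
                                  simplify = FALSE)
  for (cn in c("sl_precursor_mz_diff_abs", "sl_dot", "sl_delta", "sl_n_hits",
               "sl_hit_mean", "sl_hit_std"))
    psms[[cn]] <- NA_real_
  psms$sl_dot <- rep_len(sl_dot, n)
  rc <- paste0("reporter_", design$labels)
  for (i in seq_along(rc)) psms[[rc[i]]] <- reporters[, i]
  psms
}

# Independent brute-force evaluation of the ratio-distance formula, written
# as plain elementwise loops so it shares nothing with the implementation.
oracle_dist <- function(R, j) {
  k <- nrow(R)
  if (k == 1L) return(0)
  s <- 0
  for (i in seq_len(ncol(R))) {
    avg_rest <- mean(R[-j, i])
    avg <- mean(R[, i])
    s <- s + ((R[j, i] - avg_rest) / avg)^2
  }
  unname(sqrt(s))
}

oracle_pepdist <- function(R, peptides, j) {
  same <- which(peptides == peptides[j])
  if (length(same) >= 2L)
    return(oracle_dist(R[same, , drop = FALSE], match(j, same)))
  counts <- table(peptides)
  singles <- which(counts[peptides] == 1L)
  oracle_dist(R[singles, , drop = FALSE], match(j, singles))
}

# A feature-table row with every feature strictly inside the default filter
# bounds; tests override individual fields.
benign_features <- function(key = "run01.1.2") {
  data.frame(
    spectrum_key = key, charge = 2L, precursor_mass_da = 1500,
    peptide_length = 12L, n_ptm = 0L, ptm_ratio = 0,
    abs_mass_diff_da = 0.01, avg_reporter_intensity = 50000,
    f_value = 2, iprotdist = 0.1, ipepdist = 0.1,
    sl_precursor_mz_diff_abs = 0.005, sl_dot = 0.9, sl_delta = 0.3,
    sl_n_hits = 5, sl_hit_mean = 0.5, sl_hit_std = 0.1,
    stringsAsFactors = FALSE
  )
}

split_cond <- function(x) if (!nzchar(x)) character() else
  strsplit(x, ";", fixed = TRUE)[[1]]
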