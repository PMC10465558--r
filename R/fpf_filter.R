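# The FPF rule engine: a disjunction of feature/threshold conditions.
# A PSM is removed as soon as any evaluated condition is satisfied;
# conditions whose feature is NA for a PSM are bypassed, never triggered.

.filterable_features <- c(
  "charge", "precursor_mass_da", "peptide_length", "n_ptm", "ptm_ratio",
  "abs_mass_diff_da", "avg_reporter_intensity", "f_value",
  "iprotdist", "ipepdist",
  "sl_precursor_mz_diff_abs", "sl_dot", "sl_delta", "sl_n_hits",
  "sl_hit_mean", "sl_hit_std"
)

#' Default FPF filtering conditions
#'
#' Returns the filter configuration as a `data.frame` of conditions
#' (`feature`, `op`, `threshold`). A PSM is removed if **any** condition
#' holds; `op` is either `">="` (remove when feature >= threshold) or `"<"`
#' (remove when feature < threshold), evaluated literally, so boundary values
#' are removed by `">="` conditions and retained by `"<"` conditions.
#'
#' The nine default conditions are: charge state >= 5; precursor mass >= 4000
#' Da; peptide length >= 25; average reporter intensity < 10,000; IPepDist >=
#' 0.8; IProtDist >= 0.6; absolute mass difference >= 2 Da; spectral-library
#' dot product < 0.4; and F-value < 0.4. Features with no clear threshold
#' (PTM count/ratio and the remaining library scores) have no default
#' condition but may be added. Drop a row to disable a condition; all
#' thresholds are plain numbers and fully adjustable.
#'
#' @param conditions Optional `data.frame` with columns `feature`, `op`,
#'   `threshold` replacing the defaults entirely.
#' @return A validated condition table of class `fpf_config`.
#' @examples
#' fpf_config()                       # the nine defaults
#' cfg <- fpf_config()
#' fpf_config(cfg[cfg$feature != "f_value", ])   # disable one condition
#' @export
fpf_config <- function(conditions = NULL) {
  if (is.null(conditions)) {
    conditions <- data.frame(
      feature = c("charge", "precursor_mass_da", "peptide_length",
                  "avg_reporter_intensity", "ipepdist", "iprotdist",
                  "abs_mass_diff_da", "sl_dot", "f_value"),
      op = c(">=", ">=", ">=", "<", ">=", ">=", ">=", "<", "<"),
      threshold = c(5, 4000, 25, 10000, 0.8, 0.6, 2, 0.4, 0.4),
      stringsAsFactors = FALSE
    )
  }
  conditions <- as.data.frame(conditions, stringsAsFactors = FALSE)
  needed <- c("feature", "op", "threshold")
  if (!all(needed %in% names(conditions)))
    stop("a filter config needs columns feature, op, threshold")
  bad <- setdiff(conditions$feature, .filterable_features)
  if (length(bad))
    stop("unknown feature(s) in filter config: ", paste(bad, collapse = ", "))
  if (!all(conditions$op %in% c(">=", "<")))
    stop("condition op must be \">=\" or \"<\"")
  if (any(!is.finite(conditions$threshold)))
    stop("condition thresholds must be finite")
  rownames(conditions) <- NULL
  class(conditions) <- c("fpf_config", "data.frame")
  conditions
}

#' Apply the FPF conditions to a feature table
#'
#' Evaluates every configured condition against every PSM's features and
#' returns one decision per PSM. A condition is evaluated only when its
#' feature is present; conditions on `NA` features are listed in `bypassed`
#' and can never trigger removal. A PSM is `removed` exactly when at least
#' one evaluated condition is satisfied (`triggered` lists which, named by
#' feature, `";"`-separated).
#'
#' @param features A feature table from [featurize()].
#' @param config A condition table from [fpf_config()].
#' @return A `data.frame` with columns `spectrum_key`, `removed`,
#'   `triggered`, `bypassed`.
#' @export
apply_fpf <- function(features, config = fpf_config()) {
  config <- fpf_config(config)
  missing_feats <- setdiff(config$feature, names(features))
  if (length(missing_feats))
    stop("feature table lacks column(s): ",
         paste(missing_feats, collapse = ", "))
  n <- nrow(features)
  if (n == 0L || nrow(config) == 0L)
    return(data.frame(spectrum_key = features$spectrum_key,
                      removed = logical(n), triggered = character(n),
                      bypassed = character(n), stringsAsFactors = FALSE))
  hit <- matrix(FALSE, n, nrow(config))
  na_mat <- matrix(FALSE, n, nrow(config))
  for (ci in seq_len(nrow(config))) {
    x <- features[[config$feature[ci]]]
    na_mat[, ci] <- is.na(x)
    h <- if (config$op[ci] == ">=") x >= config$threshold[ci]
         else x < config$threshold[ci]
    hit[, ci] <- !is.na(h) & h
  }
  data.frame(
    spectrum_key = features$spectrum_key,
    removed = rowSums(hit) > 0L,
    triggered = apply(hit, 1L, function(z)
      paste(config$feature[z], collapse = ";")),
    bypassed = apply(na_mat, 1L, function(z)
      paste(config$feature[z], collapse = ";")),
    stringsAsFactors = FALSE
  )
}

#' Filter only the PSMs unique to DB+SL searching
#'
#' In the combined database + spectral-library (DB+SL) workflow, FPF is
#' applied only to PSMs that appear in the DB+SL results but not in the
#' DB-only results: the DB search is the quantitation baseline, and its PSMs
#' pass through untouched. The DB+SL PSM table is partitioned into `common`
#' (keys also found by DB searching, never filtered), `retained`
#' (DB+SL-exclusive PSMs passing FPF) and `removed` (DB+SL-exclusive PSMs
#' failing it). Features — including the ratio distances — are computed on
#' the full DB+SL table entering the filter.
#'
#' @param dbsl_psms PSM table from the DB+SL search (normalized reporters).
#' @param db_keys Character vector of [spectrum_key()]s of the valid PSMs
#'   from DB searching alone.
#' @param design A [channel_design()].
#' @param config A [fpf_config()].
#' @return A list with PSM tables `common`, `retained`, `removed`, and the
#'   per-exclusive-PSM `decisions` table from [apply_fpf()].
#' @export
filter_exclusive <- function(dbsl_psms, db_keys, design,
                             config = fpf_config()) {
  keys <- psm_keys(dbsl_psms)
  exclusive <- !(keys %in% db_keys)
  feats <- featurize(dbsl_psms, design)
  decisions <- apply_fpf(feats[exclusive, , drop = FALSE], config)
  rm_keys <- decisions$spectrum_key[decisions$removed]
  list(
    common = dbsl_psms[!exclusive, , drop = FALSE],
    retained = dbsl_psms[exclusive & !(keys %in% rm_keys), , drop = FALSE],
    removed = dbsl_psms[keys %in% rm_keys, , drop = FALSE],
    decisions = decisions
  )
}
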