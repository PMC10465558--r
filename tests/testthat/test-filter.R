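# The FPF rule engine: default conditions, bypass behavior, boundary
# conventions, and the DB+SL-exclusive application mode.

test_that("a PSM inside every bound is retained with nothing triggered", {
  dec <- apply_fpf(benign_features())
  expect_false(dec$removed)
  expect_equal(dec$triggered, "")
  expect_equal(dec$bypassed, "")
})

test_that("low intensity with outlying distances triggers exactly those
           conditions", {
  f <- benign_features()
  f$avg_reporter_intensity <- 5912
  f$ipepdist <- 1.4691
  f$iprotdist <- 1.3082
  dec <- apply_fpf(f)
  expect_true(dec$removed)
  expect_setequal(split_cond(dec$triggered),
                  c("avg_reporter_intensity", "ipepdist", "iprotdist"))
})

test_that("missing features are bypassed and never trigger", {
  # high charge with missing reporters: removed on charge alone, the three
  # reporter-dependent conditions bypassed
  f <- benign_features()
  f$charge <- 5L
  f$avg_reporter_intensity <- NA_real_
  f$iprotdist <- NA_real_
  f$ipepdist <- NA_real_
  dec <- apply_fpf(f)
  expect_true(dec$removed)
  expect_equal(split_cond(dec$triggered), "charge")
  expect_true(all(c("avg_reporter_intensity", "iprotdist", "ipepdist") %in%
                    split_cond(dec$bypassed)))

  # database-only PSM: library-score conditions are ignored, PSM retained
  f2 <- benign_features()
  f2$sl_dot <- NA_real_
  dec2 <- apply_fpf(f2)
  expect_false(dec2$removed)
  expect_true("sl_dot" %in% split_cond(dec2$bypassed))
})

test_that("boundary values follow the printed inequalities", {
  f <- benign_features()
  f$sl_dot <- 0.4                      # "< 0.4" retains the boundary
  f$avg_reporter_intensity <- 10000    # "< 10000" retains the boundary
  expect_false(apply_fpf(f)$removed)
  f$charge <- 5L                       # ">= 5" removes the boundary
  expect_true(apply_fpf(f)$removed)
  f$charge <- 2L
  f$ipepdist <- 0.8                    # ">= 0.8" removes the boundary
  expect_true(apply_fpf(f)$removed)
})

test_that("config validation rejects unknown features and bad ops", {
  expect_error(fpf_config(data.frame(feature = "nonsense", op = ">=",
                                     threshold = 1)), "unknown feature")
  expect_error(fpf_config(data.frame(feature = "charge", op = ">",
                                     threshold = 1)), "op")
  expect_error(fpf_config(data.frame(feature = "charge", op = ">=",
                                     threshold = NA_real_)), "finite")
})

make_random_features <- function(n, seed) {
  set.seed(seed)
  f <- benign_features(sprintf("run01.%d.2", seq_len(n)))
  f$charge <- sample(2:6, n, replace = TRUE)
  f$precursor_mass_da <- runif(n, 800, 6000)
  f$peptide_length <- sample(6:40, n, replace = TRUE)
  f$avg_reporter_intensity <- rlnorm(n, log(2e4), 1.5)
  f$f_value <- rnorm(n, 1.5, 1.5)
  f$iprotdist <- abs(rnorm(n, 0.4, 0.4))
  f$ipepdist <- abs(rnorm(n, 0.5, 0.5))
  f$abs_mass_diff_da <- abs(rnorm(n, 0, 1.5))
  f$sl_dot <- ifelse(runif(n) < 0.3, NA_real_, runif(n))
  f
}

test_that("filtering is idempotent and partitions the input", {
  f <- make_random_features(400, seed = 9)
  dec <- apply_fpf(f)
  expect_setequal(dec$spectrum_key, f$spectrum_key)
  expect_equal(sum(dec$removed) + sum(!dec$removed), nrow(f))
  expect_equal(dec$removed, vapply(dec$triggered, nzchar, logical(1)),
               ignore_attr = TRUE)
  retained <- f[f$spectrum_key %in% dec$spectrum_key[!dec$removed], ]
  dec2 <- apply_fpf(retained)
  expect_false(any(dec2$removed))
})

test_that("relaxing any threshold never enlarges the removed set", {
  f <- make_random_features(400, seed = 10)
  base <- apply_fpf(f)
  cfg <- fpf_config()
  for (ci in seq_len(nrow(cfg))) {
    relaxed <- cfg
    delta <- if (cfg$op[ci] == ">=") 1 else -1  # harder to satisfy
    relaxed$threshold[ci] <- relaxed$threshold[ci] + delta * 0.5
    dec <- apply_fpf(f, relaxed)
    expect_true(all(dec$spectrum_key[dec$removed] %in%
                      base$spectrum_key[base$removed]),
                info = cfg$feature[ci])
  }
})

test_that("an empty condition set removes nothing", {
  f <- make_random_features(50, seed = 11)
  dec <- apply_fpf(f, fpf_config(fpf_config()[0, ]))
  expect_false(any(dec$removed))
})

test_that("filter_exclusive touches only DB+SL-exclusive PSMs", {
  d <- generate_psms(synth_config(seed = 13, n_proteins = 30))
  psms <- normalize_reporters(d$psms, d$design)
  keys <- fpfquant:::psm_keys(psms)

  # everything common: nothing to filter
  res <- filter_exclusive(psms, keys, d$design)
  expect_equal(nrow(res$removed), 0L)
  expect_equal(nrow(res$common), nrow(psms))

  # half the keys exclusive: partition must be exact and decisions must
  # match a direct featurize + apply_fpf run on the exclusive subset
  db_keys <- keys[seq_len(nrow(psms) %/% 2)]
  res <- filter_exclusive(psms, db_keys, d$design)
  expect_equal(nrow(res$common) + nrow(res$retained) + nrow(res$removed),
               nrow(psms))
  expect_setequal(c(fpfquant:::psm_keys(res$common),
                    fpfquant:::psm_keys(res$retained),
                    fpfquant:::psm_keys(res$removed)), keys)
  feats <- featurize(psms, d$design)
  direct <- apply_fpf(feats[!(keys %in% db_keys), ])
  expect_setequal(fpfquant:::psm_keys(res$removed),
                  direct$spectrum_key[direct$removed])
})

test_that("a common PSM violating a condition still passes through", {
  psms <- toy_psms(matrix(rep(50000, 6), nrow = 2), design3,
                   charge = c(5L, 2L))   # charge 5 would trigger removal
  keys <- fpfquant:::psm_keys(psms)
  res <- filter_exclusive(psms, db_keys = keys[1], design3)
  expect_true(keys[1] %in% fpfquant:::psm_keys(res$common))
  expect_equal(nrow(res$removed), 0L)
})
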