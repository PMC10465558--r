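# Spectral features: ratios, average intensity, PTM counting, and the
# intra-protein / intra-peptide ratio distances.

test_that("psm_ratios divides by the denominator channel", {
  psms <- toy_psms(matrix(c(100, 100, 100,
                            200, 100, 50,
                            100, NA, 100), nrow = 3, byrow = TRUE), design3)
  r <- psm_ratios(psms, design3)
  expect_equal(r[1, ], c("127" = 1, "128" = 1))
  expect_equal(r[2, ], c("127" = 0.5, "128" = 0.25))
  expect_true(all(is.na(r[3, ])))  # one missing reporter voids the vector
})

test_that("a zero denominator voids the ratio vector", {
  psms <- toy_psms(matrix(c(0, 50, 50), nrow = 1), design3)
  expect_true(all(is.na(psm_ratios(psms, design3))))
})

test_that("avg_reporter_intensity averages channels, NA on any missing", {
  d2 <- channel_design(c("a", "b"))
  expect_equal(avg_reporter_intensity(
    toy_psms(matrix(c(10000, 10000, 10000), nrow = 1), design3), design3),
    10000)
  expect_equal(avg_reporter_intensity(
    toy_psms(matrix(c(5000, 7000), nrow = 1), d2), d2), 6000)
  expect_true(is.na(avg_reporter_intensity(
    toy_psms(matrix(c(5000, NA, 7000), nrow = 1), design3), design3)))
})

test_that("iprotdist matches hand-computed cases", {
  expect_equal(iprotdist(matrix(1.2, nrow = 1), 1), 0)  # lone PSM
  two_same <- matrix(c(1.3, 1.3), ncol = 1)
  expect_equal(iprotdist(two_same, 1), 0)
  expect_equal(iprotdist(two_same, 2), 0)
  # ratios 1.0 and 2.0: |1 - 2| / mean(1, 2)
  expect_equal(iprotdist(matrix(c(1, 2), ncol = 1), 1), 1 / 1.5,
               tolerance = 1e-12)
})

test_that("ipepdist uses peptide peers and the merged pseudo-peptide", {
  # lone single-hit peptide, no other singles -> 0
  expect_equal(ipepdist(matrix(1.7, nrow = 1), "AAK", 1), 0)
  # two PSMs of one peptide with identical ratios -> 0
  expect_equal(ipepdist(matrix(c(2, 2), ncol = 1), c("AAK", "AAK"), 1), 0)
  # three single-hit peptides merge: ratios 1, 1, 4; for the 4.0 PSM
  # Avg_Rest = 1, Avg = 2 -> 3/2
  R <- matrix(c(1, 1, 4), ncol = 1)
  expect_equal(ipepdist(R, c("AK", "CK", "DK"), 3), 1.5, tolerance = 1e-12)
  # a multi-hit peptide is scored against its own PSMs, not the singles
  R2 <- matrix(c(1, 1, 9), ncol = 1)
  expect_equal(ipepdist(R2, c("AK", "AK", "DK"), 1), 0)
})

test_that("a zero peer-set mean makes the distance undefined", {
  R <- matrix(c(0, 0), ncol = 1)
  expect_warning(d <- iprotdist(R, 1), "mean ratio is 0")
  expect_true(is.na(d))
})

test_that("distances agree with the brute-force oracle on random cases", {
  set.seed(42)
  for (rep in 1:200) {
    k <- sample(2:8, 1)
    n <- sample(1:9, 1)
    R <- matrix(rlnorm(k * n, 0, 0.5), nrow = k)
    peptides <- sample(paste0("PEP", 1:sample(1:k, 1)), k, replace = TRUE)
    j <- sample(k, 1)
    expect_equal(iprotdist(R, j), oracle_dist(R, j), tolerance = 1e-9)
    expect_equal(ipepdist(R, peptides, j), oracle_pepdist(R, peptides, j),
                 tolerance = 1e-9)
  }
})

test_that("distances are invariant to peer order and common ratio scaling", {
  set.seed(7)
  R <- matrix(rlnorm(5 * 3, 0, 0.4), nrow = 5)
  d0 <- iprotdist(R, 2)
  perm <- c(4, 2, 5, 1, 3)
  expect_equal(iprotdist(R[perm, ], match(2, perm)), d0, tolerance = 1e-12)
  expect_equal(iprotdist(R * 3.7, 2), d0, tolerance = 1e-12)
})

test_that("ipepdist equals iprotdist when one peptide covers the protein", {
  set.seed(8)
  R <- matrix(rlnorm(4 * 2, 0, 0.3), nrow = 4)
  pep <- rep("SAMEPEPK", 4)
  for (j in 1:4)
    expect_equal(ipepdist(R, pep, j), iprotdist(R, j), tolerance = 1e-12)
})

test_that("count_ptms excludes isobaric label tags", {
  psms <- toy_psms(matrix(rep(100, 9), nrow = 3), design3,
                   peptide = "MAAAAAAAAK")
  psms$modifications <- list(
    data.frame(position = integer(), mass_delta_da = numeric(),
               is_label = logical()),                       # unmodified
    data.frame(position = c(0L, 10L), mass_delta_da = rep(229.162932, 2),
               is_label = c(TRUE, TRUE)),                   # labels only
    data.frame(position = c(0L, 1L), mass_delta_da = c(229.162932, 15.9949),
               is_label = c(TRUE, FALSE))                   # label + oxidation
  )
  expect_equal(count_ptms(psms), c(0L, 0L, 1L))
  expect_equal(count_ptms(psms, include_labels = TRUE), c(0L, 2L, 2L))
  f <- featurize(psms, design3)
  expect_equal(f$n_ptm[3], 1L)
  expect_equal(f$ptm_ratio[3], 0.1)  # 1 PTM over length 10
})

test_that("featurize assembles the full feature vector", {
  psms <- toy_psms(matrix(c(100, 100, 100), nrow = 1), design3,
                   precursor_mass = 1501.0, calc_mass = 1500.2)
  f <- featurize(psms, design3)
  expect_equal(f$iprotdist, 0)   # only PSM of its protein
  expect_equal(f$ipepdist, 0)
  expect_equal(f$abs_mass_diff_da, 0.8, tolerance = 1e-9)
  expect_equal(f$peptide_length, nchar(psms$peptide))

  # missing reporter -> intensity and both distances enter bypass state
  psms2 <- toy_psms(matrix(c(100, NA, 100, 120, 110, 90), nrow = 2,
                           byrow = TRUE), design3)
  f2 <- featurize(psms2, design3)
  expect_true(is.na(f2$avg_reporter_intensity[1]))
  expect_true(is.na(f2$iprotdist[1]))
  expect_true(is.na(f2$ipepdist[1]))
  expect_false(is.na(f2$iprotdist[2]))
})

test_that("featurized distances match per-protein oracle on synthetic data", {
  d <- generate_psms(synth_config(seed = 31, n_proteins = 10,
                                  frac_missing_reporter = 0.1))
  psms <- normalize_reporters(d$psms, d$design)
  f <- featurize(psms, d$design)
  ratios <- psm_ratios(psms, d$design)
  complete <- stats::complete.cases(ratios)
  for (prot in unique(psms$protein)) {
    idx <- which(psms$protein == prot & complete)
    if (!length(idx)) next
    R <- ratios[idx, , drop = FALSE]
    pep <- psms$peptide[idx]
    for (j in seq_along(idx)) {
      expect_equal(f$iprotdist[idx[j]], oracle_dist(R, j), tolerance = 1e-9)
      expect_equal(f$ipepdist[idx[j]], oracle_pepdist(R, pep, j),
                   tolerance = 1e-9)
    }
  }
})
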