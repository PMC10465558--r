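---
title: "Feature-based PSM filtering for isobaric quantitation: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-based PSM filtering for isobaric quantitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpfquant)
```

# Scope and workflow

`fpfquant` operates downstream of identification: it takes validated
peptide-spectrum matches (PSMs) from iProphet-dialect pepXML — typically a
database-search (DB) result and a combined database + spectral-library
(DB+SL) result — and decides, PSM by PSM, which of the library-gained
identifications are safe to quantify. Search engines, PeptideProphet,
iProphet and library construction are upstream tools whose outputs this
package consumes; FDR estimation and protein inference stay upstream too.

The intended flow:

1. `read_pepxml()` both results; `normalize_reporters()` the DB+SL table.
2. `compare_sets()` on the key sets; only DB+SL-exclusive PSMs are
   candidates for removal (`filter_exclusive()`), because the DB result is
   the quantitation baseline every comparison is anchored to.
3. `write_filtered_pepxml()` emits a file the rest of TPP accepts.
4. `protein_quant_sum()`, `psm_are()`, `coverage_auc()` evaluate the
   outcome when theoretical ratios are known.

# The spectral features

Sixteen features are computed per PSM (`featurize()`). Ten are general:
charge state, precursor neutral mass (Da), peptide length, PTM count, PTM
ratio (count / length), absolute mass difference |observed − theoretical|
(Da), average normalized reporter intensity, the PeptideProphet F-value,
and the two ratio-distance features below. Six exist only for PSMs matched
by the spectral library: absolute precursor m/z difference, dot product,
delta score, number of hits, hit mean, hit standard deviation. Any feature
that cannot be computed is `NA`, and the filter *bypasses* conditions on
`NA` features — a PSM can only be removed on evidence that exists.

## Ratio distances

With `k` channels and denominator channel `d`, each PSM has
`n = k − 1` ratios `R_i = intensity_i / intensity_d` (after
normalization). For PSM `j` among the PSMs of one protein,

$$IProtDist_j = \sqrt{\sum_{i=1}^{n}
  \left(\frac{R_i^j - AvgRest_i}{Avg_i}\right)^2},$$

with `AvgRest_i` the mean of ratio `i` over the other PSMs and `Avg_i` the
mean over all of them. The normalization by `Avg_i` makes the distance
scale-free: multiplying every peer's ratio vector by a common constant
leaves it unchanged (a tested property). A PSM alone in its peer set scores
0 — no evidence of disagreement.

`IPepDist` restricts peers to PSMs of the same peptide sequence. Peptides
identified by a single PSM have no peers, so all single-hit peptides of a
protein are merged into one *pseudo-peptide* and scored within that merged
set; a PSM alone even there scores 0.

Decisions that the formula text leaves open, resolved here once:

* **Peer grouping** uses the primary (first-listed) protein accession.
  Shared peptides contribute only to that protein's peer set; grouping is
  thereby deterministic regardless of how accessions are ordered elsewhere.
* **Peers must have complete ratio vectors.** A PSM with a missing reporter
  ion has no ratio vector, so it neither receives a distance (bypass) nor
  distorts its peers' means. Peptide single-hit status is likewise counted
  within the complete-ratio subset.
* **Peptide identity** for peer grouping is the stripped sequence; charge
  and modification variants of one sequence count as the same peptide.
* **A zero peer-set mean** (possible when a numerator channel is entirely
  zero-intensity across peers) makes the distance undefined; it becomes
  `NA` with a warning, i.e. the bypass path, rather than an infinity.

## PTM counting

Isobaric label tags (TMT/iTRAQ reagent masses, recognized by mass delta)
are excluded from the PTM count by default: labels sit on essentially every
peptide of a labeled experiment, so counting them would shift the feature
by a constant and erase its signal. `count_ptms(include_labels = TRUE)`
restores the literal count for users who disagree.

# The filter

`fpf_config()` holds the conditions; a PSM is removed when **any** holds.
The nine defaults (charge ≥ 5, mass ≥ 4000 Da, length ≥ 25, average
reporter intensity < 10,000, IPepDist ≥ 0.8, IProtDist ≥ 0.6, |Δm| ≥ 2 Da,
dot < 0.4, F-value < 0.4) reflect where the frequency of large-error PSMs
jumps when binned by each feature (`frequency_by_feature()` reproduces that
analysis). Features without a clear jump — PTM count/ratio and the
remaining library scores — ship with no default condition but accept
user-configured ones.

Numerical conventions, chosen once and tested:

* **Boundaries follow the printed inequalities literally**: `≥` conditions
  remove the boundary value, `<` conditions retain it (dot exactly 0.4
  survives; charge exactly 5 does not).
* **Bypass is per condition, not per PSM**: a PSM with missing reporters
  skips the intensity and distance conditions but is still subject to
  charge, mass, length, |Δm|, F-value and any library-score conditions.
* The engine is deterministic and idempotent, removal is monotone in every
  threshold, and retained/removed partition the input — all enforced by
  property tests.

# Normalization and quantitation

`normalize_reporters()` rescales each channel by `reference / median(channel)`,
with the reference set to the median of the per-channel medians. Any common
reference produces identical ratios (ratios are reference-invariant); this
choice merely keeps intensities near their original magnitude. A channel
with no observed values is an error, not a silent skip. A reporter recorded
as absent **or exactly 0** upstream is treated as missing throughout — the
bypass and eligibility rules need an unambiguous missing state, and a true
zero intensity is indistinguishable from a failed reporter measurement.

`protein_quant_sum()` implements SumPsmIntensity only: per protein, sum
each channel over eligible PSMs (unique peptide, complete reporters), then
form ratios from the sums. Median- or weighted-PSM-ratio protein summaries
are deliberately out of scope.

`psm_are()` is the mean relative deviation from the theoretical ratios.
`coverage_auc()` integrates the empirical CDF of ARE over `[0, max_are]`
and divides by `max_are`; the step function is integrated exactly (for
values `a_i`, the area is `mean(max_are − min(a_i, max_are))`), which a
trapezoid on the step knots approaches from below. The cap defaults to
ARE = 1 — beyond 100% mean error, differences carry no practical
information — and is configurable; published AUC values from other
pipelines depend on their (unstated) integration range and are not claimed
reproducible here.

The top-ARE quartile labeling (`label_large_error()`, default fraction
0.25) takes the `ceiling(0.25 N)` largest; ties at the cutoff break by
ascending spectrum key so the label set is reproducible.

# Precursor purity (S2I)

`compute_s2i()` divides the intensity of the precursor and its isotopic
cluster by the total intensity inside the isolation window. Defaults:
isotopes `k = 0..4` at spacing 1.00335 Da / charge, 10 ppm matching
tolerance, ±0.85 Th window when the mzML lacks isolation metadata — all
three exposed as arguments, since instrument conventions vary. The MS1
scan is the nearest one preceding the MS2 trigger; interpolation between
bracketing MS1 scans is a refinement some vendors apply that is
intentionally not reproduced. The 0.7 threshold filter (`s2i_filter()`)
belongs to the library-construction path, not to the FPF input; PSMs
without an MS1 context pass with a warning rather than being silently
dropped. An empty isolation window yields S2I 0 (no evidence of purity).

# The synthetic generator

`generate_psms()` exists so every stage is testable against known ground
truth without multi-GB raw data. It emulates an equimolar 6-plex
experiment: reporter intensities are `base × theoretical ratio ×
multiplicative lognormal noise`, with `sdlog = sqrt(log(1 + cv²))` so the
configured coefficient of variation is exact, and the noise mean-corrected
(`meanlog = −sdlog²/2`) so channel expectations stay on the theoretical
ratios. Defaults, chosen once as typical of a TMT benchmark mixture:
400 proteins × ~10 PSMs (negative binomial, dispersion 5), lognormal base
intensity with median 50,000 counts and sdlog 1, 10% ratio-noise CV, 25%
"bad" PSMs at 5× that CV, 2% missing-reporter PSMs, 5% shared peptides,
half the PSMs carrying library scores. With feature coupling on (default),
bad PSMs are biased toward low base intensity, lengths ≥ 25 and charges
≥ 5 — the correlations the filter's conditions exploit.

What it does **not** emulate: co-isolation physics (bad PSMs are modeled
as inflated ratio noise, not interference-shifted means — this inflates
error without biasing protein ratios), chromatography, isotope impurity of
the labels, charge-dependent fragmentation quality, or realistic F-value /
dot-product score distributions for incorrect identifications. Passing the
end-to-end tests therefore shows the pipeline removes PSMs whose errors
correlate with its features; it does not certify effect sizes on real
data, where the coupling strengths are dataset properties.

All sampling flows from one RNG stream seeded by `synth_config(seed=)` in
a fixed order, so output is byte-stable across runs, and the generator
restores the caller's RNG state.

# Problem sizes and runtime

The test suite and `scripts/acceptance.R` use simulations of roughly 4000
PSMs (400 proteins) for the end-to-end efficacy checks, 10^5 draws for the
uniform-ARE AUC check, and 1000 random small instances (≤ 8 PSMs, ≤ 9
ratios) for the brute-force distance oracle — sizes at which every
behavior under test is already stable while the whole suite runs in well
under a minute.

# Known limitations

* pepXML reading keeps only the rank-1 hit per spectrum query and expects
  Libra-style intensity elements (or a sidecar TSV via
  `read_psm_table()`); Mascot/MaxQuant exports are out of scope.
* `write_filtered_pepxml()` preserves upstream `analysis_summary` counts
  verbatim, so header counts can disagree with the remaining queries after
  filtering; recomputing them would mean re-deriving upstream statistics
  the package does not own.
* Set comparison is spectrum-key based; a spectrum identified by both
  searches with *different* peptides still counts as common.
* The filter is rule-based by design; no learned score is fitted, so its
  thresholds are only as good as the data they were derived from, and
  datasets with different noise structure may need adjusted cutoffs.
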