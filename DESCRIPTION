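Package: fpfquant
Title: Feature-Based PSM Filtering for Isobaric Labeling Quantitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for improving the accuracy of isobaric labeling (TMT/iTRAQ)
    quantitation from Trans-Proteomic Pipeline identification results. Reads
    and writes iProphet-dialect pepXML, computes per-PSM spectral features
    including the intra-protein and intra-peptide ratio-distance measures,
    applies a rule-based feature filter (FPF) to peptide-spectrum matches,
    normalizes reporter-ion intensities by channel medians, quantifies
    proteins by summed reporter intensity, evaluates accuracy with average
    relative error (ARE) and coverage-versus-ARE AUC, computes precursor
    signal-to-interference (S2I) from MS1 scans, compares identification sets
    from database versus database-plus-spectral-library searching, and
    generates synthetic multi-channel PSM data sets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    mzR,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
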