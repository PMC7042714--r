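Package: secshift
Title: Differential Protein Complex Association from SEC Co-Fractionation Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative and differential analysis of protein complex
    profiles from size-exclusion chromatography coupled to data-independent
    acquisition mass spectrometry (SEC-SWATH-MS / co-fractionation MS).
    Takes long-format peptide-level fractionation intensity tables through
    spike-in normalization, spline-based gap imputation, consecutive-run and
    sibling-peptide-correlation filtering with target-decoy error control,
    protein elution-peak (feature) detection with decoy-based q-values,
    SEC-localized paired differential association testing with
    order-statistic (beta) aggregation of peptide-level p-values and
    Benjamini-Hochberg correction, classification of significant changes,
    and inference of protein complex remodeling from complex priors. Includes
    a fully seeded synthetic-data generator emulating the statistical
    structure of SEC-SWATH-MS experiments so every stage is testable with
    known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
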