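Package: pulsedms
Title: Pulsed Direct-Infusion Mass Spectrometry Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pulsed nanoelectrospray direct-infusion
    mass spectrometry metabolomics of volume-limited samples. Processes
    scan-level data into representative spectra via chronogram pulse
    detection, internal-standard pulse quality control and random pulse
    selection; aligns spectra into a feature table and applies blank,
    prevalence, QC-missingness and RSD filters with half-minimum imputation
    and internal-standard normalization; runs the statistical stage
    (generalized-log transform, autoscaling, Welch tests, fold changes,
    PLS-DA with VIP scores, orthogonal PLS-DA with leave-one-out
    cross-validation, PCA, Pearson correlation); and annotates features by
    accurate mass against candidate formula lists with common adducts. A
    seeded synthetic pulse-train generator emulates the acquisition so the
    whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    mixOmics,
    mzR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
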