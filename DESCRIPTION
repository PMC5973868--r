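Package: lipidsign
Title: Class-Level Lipidomics Sign Tests, Isotopologue Enrichment and
    Tumor Growth Metrics for Preclinical Xenograft Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Differential lipidomics analysis for preclinical
    patient-derived xenograft (PDX) studies: total-intensity
    normalization, offset log-transform, detection-presence filtering,
    patient-centered log fold-changes, per-lipid one-sample t-tests, and
    an exact class-level binomial sign test whose effect statistic is the
    log-ratio of the observed success proportion to 0.5.  Also provides
    exact-mass peak assignment of FT-MS peak lists at ppm tolerance,
    natural-abundance 13C isotopologue correction with absolute and
    fractional enrichments for stable-isotope-resolved metabolomics,
    Wilcoxon rank-sum tests with Storey q-values for cohort metabolite
    panels, caliper-based tumor volume and AUC-based growth-inhibition
    metrics with bootstrap confidence intervals, immunoreactivity
    scoring, and a seeded synthetic-data generator that emulates the
    control-versus-treated PDX design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
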