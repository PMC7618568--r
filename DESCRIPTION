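Package: woodburnr
Title: Small-Area Mapping of Residential Wood-Burning Heat Sources from
    Energy Performance Certificates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for estimating the prevalence and spatial
    concentration of residential wood and solid-fuel heat sources from
    Energy Performance Certificate (EPC) registers. Certificates are
    deduplicated, classified by keyword search over free-text heat-source
    descriptions, harmonised to Census property-type and tenure categories
    and linked to small-area geographies. Census post-stratification
    corrects the selection bias of the EPC register; per-geography
    prevalence and concentration estimates are aggregated across a
    geographic hierarchy and truncated for mapping. The concentration
    metric is validated against hourly PM2.5 from air-quality monitors via
    circular-buffer and grid-square burner counts, a winter-evening
    peak/off-peak difference statistic, and Spearman correlations with
    bias-corrected accelerated (BCa) bootstrap intervals. Beta regression
    with a logit link relates small-area prevalence to socio-economic
    covariates. A seeded synthetic-data generator emulates every input with
    known ground truth so the full pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    boot,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
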