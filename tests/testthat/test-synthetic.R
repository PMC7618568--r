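# Synthetic generator: geography, registry, monitoring, determinism.

test_that("scenario_config validates its inputs", {
  cfg <- scenario_config(seed = 5)
  expect_s3_class(cfg, "scenario_config")
  expect_error(scenario_config(nonsense_key = 1), "unknown config keys")
  expect_error(scenario_config(n_rows = 0L), "n_rows")
  expect_error(scenario_config(inclusion_prob = c(detached = 1.5,
                                                  semi_detached = 0.5,
                                                  terrace = 0.5, flat = 0.5,
                                                  other = 0.5)))
})

test_that("a 4x4 grid yields 16 LSOAs of exactly 1 km2", {
  cfg <- scenario_config(seed = 2, n_rows = 4L, n_cols = 4L,
                         urban_cols = 2L, sca_cols = 1L)
  geo <- generate_geography(cfg)
  expect_length(geo$polys, 16)
  expect_true(all(vapply(geo$polys, polygon_area, numeric(1)) == 1e6))
  expect_equal(geo$areas$area_km2, rep(1, 16))
  # nested hierarchy: every LSOA has one ward/lad/region
  expect_equal(nrow(geo$hierarchy), 16)
  expect_false(anyDuplicated(geo$hierarchy$lsoa) > 0)
  # urban/SCA blocks and SCA within the urban block
  expect_equal(sum(geo$covariates$urban), 8)
  expect_true(all(geo$covariates$urban[geo$covariates$sca]))
})

test_that("covariate draws match their configured distributions", {
  # 10,000 LSOAs: MC error on the means is tiny
  cfg <- scenario_config(seed = 3, n_rows = 100L, n_cols = 100L,
                         urban_cols = 50L, sca_cols = 20L)
  geo <- generate_geography(cfg)
  cov <- geo$covariates
  expect_equal(mean(cov$imd_score), cfg$imd_shape * cfg$imd_scale,
               tolerance = 0.03)
  expect_equal(mean(cov$median_age[cov$urban]), cfg$age_mean_urban,
               tolerance = 0.01)
  expect_equal(mean(cov$median_age[!cov$urban]), cfg$age_mean_rural,
               tolerance = 0.01)
  expect_true(all(cov$median_age >= 25 & cov$median_age <= 65))
  expect_true(all(cov$pct_white > 0 & cov$pct_white < 100))
})

test_that("lookup is a function of UPRN and plants unmatched records", {
  cfg <- scenario_config(seed = 4, n_rows = 5L, n_cols = 5L,
                         urban_cols = 2L, sca_cols = 1L)
  scn <- generate_scenario(cfg, monitoring = FALSE)
  lk <- scn$registry$lookup
  expect_equal(anyDuplicated(lk$uprn), 0L)
  n_props <- nrow(scn$registry$properties)
  expect_equal(nrow(lk) + length(scn$registry$truth$unmatched_uprns),
               n_props)
  expect_equal(length(scn$registry$truth$unmatched_uprns),
               floor(cfg$unmatched_rate * n_props))
})

test_that("saturated inclusion makes EPC counts equal Census counts", {
  cfg <- scenario_config(
    seed = 6, n_rows = 4L, n_cols = 4L, urban_cols = 2L, sca_cols = 1L,
    inclusion_prob = c(detached = 1, semi_detached = 1, terrace = 1,
                       flat = 1, other = 1),
    n_certs_probs = c(1, 0, 0, 0), duplication_rate = 0,
    unmatched_rate = 0)
  scn <- generate_scenario(cfg, monitoring = FALSE)
  certs <- scn$registry$certificates
  # exactly one certificate per property
  expect_equal(nrow(certs), nrow(scn$registry$properties))
  tab <- as.data.frame(table(
    lsoa = scn$registry$properties$lsoa,
    property_type = scn$registry$properties$property_type))
  m <- merge(tab, scn$registry$census, by = c("lsoa", "property_type"))
  expect_equal(m$Freq, m$n_census)
})

test_that("register text is exactly invertible to the planted wood flags", {
  cfg <- scenario_config(seed = 7, n_rows = 6L, n_cols = 6L,
                         urban_cols = 3L, sca_cols = 2L,
                         duplication_rate = 0)
  scn <- generate_scenario(cfg, monitoring = FALSE)
  certs <- scn$registry$certificates
  cl <- classify_heat_source(certs$mainheat_text, certs$secondheat_text)
  certs$wood_fuel <- cl$wood_fuel
  latest <- flag_most_recent(certs)
  latest <- latest[latest$is_latest, ]
  props <- scn$registry$properties
  m <- match(latest$uprn, props$uprn)
  expect_equal(latest$wood_fuel, props$wood_final[m])
  # distractor text never flips a classification
  cfg_noisy <- scenario_config(seed = 7, n_rows = 6L, n_cols = 6L,
                               urban_cols = 3L, sca_cols = 2L,
                               duplication_rate = 0, noisy_text = TRUE)
  scn2 <- generate_scenario(cfg_noisy, monitoring = FALSE)
  cl2 <- classify_heat_source(scn2$registry$certificates$mainheat_text,
                              scn2$registry$certificates$secondheat_text)
  latest2 <- scn2$registry$certificates
  latest2$wood_fuel <- cl2$wood_fuel
  latest2 <- flag_most_recent(latest2)
  latest2 <- latest2[latest2$is_latest, ]
  m2 <- match(latest2$uprn, scn2$registry$properties$uprn)
  expect_equal(latest2$wood_fuel, scn2$registry$properties$wood_final[m2])
})

test_that("empirical wood prevalence matches the model-implied mean", {
  cfg <- scenario_config(seed = 8, n_rows = 10L, n_cols = 10L,
                         urban_cols = 5L, sca_cols = 2L)
  geo <- generate_geography(cfg)
  reg <- generate_registry(cfg, geo)
  pr <- reg$properties
  cov <- geo$covariates
  li <- match(pr$lsoa, cov$lsoa)
  wm <- cfg$wood_model
  eta <- wm$intercept + wm$imd * cov$imd_score[li] +
    wm$age * cov$median_age[li] + wm$urban * cov$urban[li] +
    wm$type_effects[pr$property_type]
  implied <- mean(plogis(eta))
  observed <- mean(pr$wood0)
  # MC error: 3 binomial standard deviations
  expect_lt(abs(observed - implied),
            3 * sqrt(implied * (1 - implied) / nrow(pr)))
})

test_that("deduplication removes exactly the planted duplicates", {
  cfg <- scenario_config(seed = 9, n_rows = 6L, n_cols = 6L,
                         urban_cols = 3L, sca_cols = 2L)
  scn <- generate_scenario(cfg, monitoring = FALSE)
  certs <- scn$registry$certificates
  dd <- deduplicate_certificates(certs)
  expect_equal(attr(dd, "n_removed"),
               scn$registry$truth$n_planted_duplicates)
  expect_equal(nrow(certs) - nrow(dd),
               scn$registry$truth$n_planted_duplicates)
})

test_that("kappa = 0 leaves no expected peak/off-peak difference", {
  cfg <- scenario_config(seed = 10, n_monitors = 10L, n_other_sites = 0L,
                         monitor_years = c(2023L, 2023L), kappa = 0,
                         missing_rate = 0)
  scn <- generate_scenario(cfg)
  po <- peak_offpeak_diff(scn$monitoring$measurements, "winter", "all")
  # mean across sites ~ N(0, sigma * sqrt(1/n_peak + 1/n_off) / sqrt(10))
  se <- cfg$sigma * sqrt(1 / mean(po$n_peak) + 1 / mean(po$n_offpeak)) /
    sqrt(nrow(po))
  expect_lt(abs(mean(po$peak_diff)), 4 * se)
})

test_that("true density ranks agree with point-mode buffer counts", {
  cfg <- scenario_config(seed = 12, n_monitors = 20L, n_other_sites = 0L,
                         monitor_years = c(2023L, 2023L))
  scn <- generate_scenario(cfg)
  sites <- scn$monitoring$sites
  pr <- scn$registry$properties
  burners <- pr[pr$wood_final, c("x", "y")]
  by_point <- vapply(seq_len(nrow(sites)), function(i)
    buffer_count(NULL, NULL, c(sites$easting[i], sites$northing[i]), 1000,
                 mode = "point", points = burners), numeric(1))
  expect_equal(by_point, sites$true_burners_1km)
  expect_equal(spearman_r(by_point, sites$true_density), 1)
})

test_that("writing a scenario is byte-identical under the same seed", {
  cfg <- scenario_config(seed = 13, n_rows = 5L, n_cols = 5L,
                         urban_cols = 3L, sca_cols = 1L,
                         n_monitors = 3L, n_other_sites = 1L,
                         monitor_years = c(2023L, 2023L))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- write_scenario(generate_scenario(cfg), d1)
  f2 <- write_scenario(generate_scenario(cfg), d2)
  expect_equal(basename(unname(f1)), basename(unname(f2)))
  for (i in seq_along(f1))
    expect_equal(unname(tools::md5sum(f1[i])), unname(tools::md5sum(f2[i])),
                 label = basename(f1[i]))
  # a different seed changes the register
  cfg2 <- cfg; cfg2$seed <- 14L
  d3 <- withr::local_tempdir()
  f3 <- write_scenario(generate_scenario(cfg2), d3)
  expect_false(unname(tools::md5sum(f1[["epc"]])) ==
                 unname(tools::md5sum(f3[["epc"]])))
})
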