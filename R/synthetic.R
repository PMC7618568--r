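#' Scenario configuration for the synthetic-data generator
#'
#' Defines every knob of the synthetic study region: a rectangular grid of
#' square LSOA cells, property stocks by type, type-dependent EPC inclusion
#' probabilities (the selection bias the Census correction must remove), a
#' logistic model for wood-burner presence, certificate duplication and
#' repeat-certificate installation rates, and an hourly PM2.5 model with
#' seasonal background plus a winter-evening wood-smoke component
#' proportional to the local burner density.
#'
#' Defaults describe a plausible small English study region: 144 LSOAs of
#' 1 km2 (~410 properties each), EPC coverage lowest for detached houses
#' (0.40) and highest for flats (0.90), wood-burner log-odds decreasing in
#' deprivation (-0.012 per IMD unit) and urbanicity and increasing with
#' age, ~3% duplicated certificates, 30% of properties with repeat
#' certificates, 5% wood-burner installation probability between
#' certificates, and 60 urban-background monitors with two years of hourly
#' PM2.5 (background 8 ug/m3, winter-peaking seasonal amplitude 3,
#' noise sd 2, wood term kappa = 0.05 ug/m3 per burner/km2 on peak winter
#' hours). The diurnal-cycle amplitude defaults to 0 so the peak/off-peak
#' statistic isolates the planted wood term exactly in expectation.
#'
#' @param seed integer master seed; all generators derive their RNG state
#'   from it.
#' @param ... overrides for any default listed above (see the function
#'   definition for names).
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_rows = 12L, n_cols = 12L, cell_m = 1000,
    urban_cols = 6L,   # columns 1..urban_cols are urban (contiguous block)
    sca_cols = 3L,     # columns 1..sca_cols are a smoke control area
    properties_per_lsoa = c(detached = 80, semi_detached = 120,
                            terrace = 140, flat = 60, other = 10),
    inclusion_prob = c(detached = 0.40, semi_detached = 0.60,
                       terrace = 0.80, flat = 0.90, other = 0.50),
    wood_model = list(intercept = -3.2, imd = -0.012, age = 0.02,
                      urban = -0.5,
                      type_effects = c(detached = 1.0, semi_detached = 0,
                                       terrace = -0.45, flat = -2.5,
                                       other = -1.0)),
    coal_rate = 0.01,           # solid-but-not-wood heat sources
    wood_as_main_rate = 0.05,   # wood in the main (vs secondary) field
    duplication_rate = 0.03,
    n_certs_probs = c(0.70, 0.225, 0.060, 0.015),  # P(1..4 certificates)
    installation_rate = 0.05,   # non-wood -> wood between certificates
    unmatched_rate = 0.02,      # UPRNs absent from the geography lookup
    new_build_rate = 0.05,
    study_window = as.Date(c("2009-01-01", "2025-02-28")),
    imd_shape = 2, imd_scale = 10,
    age_mean_urban = 40, age_mean_rural = 46, age_sd = 5,
    age_range = c(25, 65),
    white_logit_mean_urban = stats::qlogis(0.80),
    white_logit_mean_rural = stats::qlogis(0.95),
    white_logit_sd = 0.8,
    population_range = c(1000, 3000),
    noisy_text = FALSE,
    n_monitors = 60L, n_other_sites = 5L,
    monitor_years = c(2023L, 2024L),
    buffer_radius_m = 1000,
    pm25_background = 8, pm25_seasonal_amp = 3, pm25_diurnal_amp = 0,
    kappa = 0.05, sigma = 2, missing_rate = 0.05,
    peak_hours = c(19:23, 0L), offpeak_hours = 5:16
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$n_rows > 0, cfg$n_cols > 0, cfg$cell_m > 0,
            all(cfg$inclusion_prob >= 0 & cfg$inclusion_prob <= 1),
            cfg$kappa >= 0, cfg$sigma >= 0,
            abs(sum(cfg$n_certs_probs) - 1) < 1e-8)
  structure(cfg, class = "scenario_config")
}

ptype_levels <- c("detached", "semi_detached", "terrace", "flat", "other")

#' Generate the synthetic geography
#'
#' Square LSOA cells tiling a rectangle, with nested ward (2x2 cells), LAD
#' (4x4) and region (8x8) codes, LSOA covariates (IMD ~ Gamma, median age ~
#' truncated Normal, percent white ~ logit-Normal, urban and SCA as
#' contiguous column blocks) and per-LSOA areas.
#'
#' @param cfg a [scenario_config()].
#' @return list with `polys` (named list of vertex matrices), `covariates`,
#'   `hierarchy`, `areas` (data.frames) and `cells` (cell bookkeeping).
#' @export
generate_geography <- function(cfg) {
  set.seed(cfg$seed + 1L)
  n <- cfg$n_rows * cfg$n_cols
  row <- rep(seq_len(cfg$n_rows) - 1L, each = cfg$n_cols)
  col <- rep(seq_len(cfg$n_cols) - 1L, times = cfg$n_rows)
  lsoa <- sprintf("L%04d", seq_len(n))
  cm <- cfg$cell_m
  polys <- stats::setNames(lapply(seq_len(n), function(i) {
    x0 <- col[i] * cm; y0 <- row[i] * cm
    rbind(c(x0, y0), c(x0 + cm, y0), c(x0 + cm, y0 + cm), c(x0, y0 + cm))
  }), lsoa)
  hierarchy <- data.frame(
    lsoa = lsoa,
    ward = sprintf("W%03d", (row %/% 2L) * 100L + (col %/% 2L)),
    lad = sprintf("D%03d", (row %/% 4L) * 100L + (col %/% 4L)),
    region = sprintf("R%02d", (row %/% 8L) * 10L + (col %/% 8L)))
  urban <- col < cfg$urban_cols
  sca <- col < cfg$sca_cols
  age_mean <- ifelse(urban, cfg$age_mean_urban, cfg$age_mean_rural)
  age <- stats::rnorm(n, age_mean, cfg$age_sd)
  age <- pmin(pmax(age, cfg$age_range[1]), cfg$age_range[2])
  wmean <- ifelse(urban, cfg$white_logit_mean_urban,
                  cfg$white_logit_mean_rural)
  covariates <- data.frame(
    lsoa = lsoa,
    imd_score = stats::rgamma(n, shape = cfg$imd_shape,
                              scale = cfg$imd_scale),
    median_age = age,
    pct_white = 100 * stats::plogis(stats::rnorm(n, wmean,
                                                 cfg$white_logit_sd)),
    urban = urban, sca = sca,
    region = hierarchy$region,
    population = round(stats::runif(n, cfg$population_range[1],
                                    cfg$population_range[2])))
  areas <- data.frame(lsoa = lsoa, area_km2 = (cm / 1000)^2)
  cells <- data.frame(lsoa = lsoa, row = row, col = col,
                      x0 = col * cm, y0 = row * cm)
  list(polys = polys, covariates = covariates, hierarchy = hierarchy,
       areas = areas, cells = cells)
}

heat_text_templates <- list(
  none_main = c("Boiler and radiators, mains gas",
                "Electric storage heaters",
                "Air source heat pump, radiators",
                "Boiler and radiators, oil"),
  wood = c("Room heaters, wood logs", "Boiler and radiators, wood pellets",
           "Room heaters, biomass", "Stove, wood chip"),
  coal = c("Room heaters, coal", "Boiler, anthracite",
           "Room heaters, smokeless fuel"),
  none_second = c("", "None", "Room heaters, electric"),
  distractors = c("community scheme", "underfloor heating",
                  "secondary glazing throughout", "no heating controls"))

render_heat_text <- function(wood, coal, cfg) {
  n <- length(wood)
  main <- sample(heat_text_templates$none_main, n, replace = TRUE)
  second <- sample(heat_text_templates$none_second, n, replace = TRUE)
  wmain <- wood & (stats::runif(n) < cfg$wood_as_main_rate)
  wtxt <- sample(heat_text_templates$wood, n, replace = TRUE)
  main[wood & wmain] <- wtxt[wood & wmain]
  second[wood & wmain] <- "None"
  second[wood & !wmain] <- wtxt[wood & !wmain]
  ctxt <- sample(heat_text_templates$coal, n, replace = TRUE)
  second[coal & !wood] <- ctxt[coal & !wood]
  if (isTRUE(cfg$noisy_text)) {
    extra <- sample(heat_text_templates$distractors, n, replace = TRUE)
    main <- paste(main, extra, sep = ", ")
  }
  list(main = main, second = second)
}

raw_type_fields <- function(type) {
  pt <- c(detached = "House", semi_detached = "House", terrace = "House",
          flat = "Flat", other = "Park home")[type]
  bf <- c(detached = "Detached", semi_detached = "Semi-Detached",
          terrace = "Mid-Terrace", flat = "", other = "")[type]
  list(property_type_raw = unname(pt), built_form_raw = unname(bf))
}

#' Generate the synthetic certificate register and Census stock
#'
#' Draws the full property stock (Poisson counts per LSOA x type, uniform
#' coordinates within the LSOA cell), assigns each property a wood-burner
#' status from the logistic model, simulates a certificate history for
#' every property (count, dates, and possible wood-burner installation
#' between certificates — installations are monotone), and emits
#' certificates only for the biased EPC-included subset. The Census stock
#' records the full property counts; certificate free text is rendered from
#' keyword templates so classification is exactly invertible. Duplicate
#' certificate rows are planted at the configured rate, and a fraction of
#' UPRNs is withheld from the geography lookup.
#'
#' A property's ground-truth wood flag is its status at its latest
#' (simulated) certificate; because the certificate process is simulated
#' for every property and EPC inclusion is independent of it, truth and
#' register agree in distribution within strata.
#'
#' @param cfg a [scenario_config()].
#' @param geography output of [generate_geography()].
#' @return list: `properties` (per-property truth incl. coordinates),
#'   `certificates` (register rows, standardised names), `census` (stock
#'   counts), `lookup` (UPRN to geography, with planted unmatched UPRNs
#'   removed), `truth` (per-LSOA summary and planted bookkeeping).
#' @export
generate_registry <- function(cfg, geography) {
  set.seed(cfg$seed + 2L)
  cov <- geography$covariates
  cells <- geography$cells
  nl <- nrow(cov)
  counts <- matrix(stats::rpois(nl * length(ptype_levels),
                                rep(cfg$properties_per_lsoa[ptype_levels],
                                    each = nl)),
                   nrow = nl,
                   dimnames = list(cov$lsoa, ptype_levels))
  props <- data.table(
    lsoa = rep(rep(cov$lsoa, length(ptype_levels)), times = as.vector(counts)),
    property_type = rep(rep(ptype_levels, each = nl), times = as.vector(counts)))
  np <- nrow(props)
  props[, uprn := sprintf("U%07d", seq_len(np))]
  li <- match(props$lsoa, cov$lsoa)
  props[, `:=`(x = cells$x0[li] + stats::runif(np) * cfg$cell_m,
               y = cells$y0[li] + stats::runif(np) * cfg$cell_m)]
  wm <- cfg$wood_model
  eta <- wm$intercept + wm$imd * cov$imd_score[li] +
    wm$age * cov$median_age[li] + wm$urban * cov$urban[li] +
    wm$type_effects[props$property_type]
  props[, wood0 := stats::runif(np) < stats::plogis(eta)]
  props[, coal := !wood0 & stats::runif(np) < cfg$coal_rate]
  # certificate history for every property; emission is a separate draw
  props[, n_certs := sample.int(length(cfg$n_certs_probs), np,
                                replace = TRUE, prob = cfg$n_certs_probs)]
  props[, installs := stats::rbinom(np, pmax(n_certs - 1L, 0L),
                                    cfg$installation_rate)]
  # monotone: a non-wood property with >=1 install between certificates is
  # wood by its latest certificate
  props[, wood_final := wood0 | installs > 0L]
  props[, included := stats::runif(np) <
          cfg$inclusion_prob[props$property_type]]
  props[, new_build := stats::runif(np) < cfg$new_build_rate]
  props[, tenure_raw := sample(c("Owner-occupied", "Rented (private)",
                                 "Rented (social)"), np, replace = TRUE,
                               prob = c(0.62, 0.20, 0.18))]

  # installs > 0 means the property turns wood from certificate
  # `switch_at` (uniform over 2..n_certs) onwards
  props[, switch_at := fifelse(installs > 0L & n_certs > 1L,
                               2L + as.integer(floor(stats::runif(np) *
                                                       (n_certs - 1L))),
                               NA_integer_)]
  # expand certificates for included properties; certificate order is
  # inspection-date order
  inc <- props[included == TRUE]
  cert <- inc[rep(seq_len(nrow(inc)), inc$n_certs)]
  win <- as.numeric(cfg$study_window)
  cert[, dval := stats::runif(.N, win[1], win[2])]
  setorder(cert, uprn, dval)
  cert[, ord := seq_len(.N), by = uprn]
  cert[, inspection_date := as.Date(floor(dval), origin = "1970-01-01")]
  cert[, dval := NULL]
  cert[, wood_at_cert := wood0 | (!is.na(switch_at) & ord >= switch_at)]

  nc <- nrow(cert)
  cert[, certificate_id := sprintf("C%09d", sample.int(10 * nc, nc))]
  txt <- render_heat_text(cert$wood_at_cert, cert$coal, cfg)
  rawt <- raw_type_fields(cert$property_type)
  certificates <- data.frame(
    certificate_id = cert$certificate_id,
    uprn = cert$uprn,
    inspection_date = cert$inspection_date,
    property_type_raw = rawt$property_type_raw,
    built_form_raw = rawt$built_form_raw,
    tenure_raw = cert$tenure_raw,
    transaction_type_raw = ifelse(cert$new_build & cert$ord == 1L,
                                  "new dwelling", "marketed sale"),
    mainheat_text = txt$main,
    secondheat_text = txt$second)
  n_dup <- floor(cfg$duplication_rate * nrow(certificates))
  if (n_dup > 0) {
    dup_rows <- sample.int(nrow(certificates), n_dup)
    certificates <- rbind(certificates, certificates[dup_rows, ])
    certificates <- certificates[sample.int(nrow(certificates)), ]
    rownames(certificates) <- NULL
  }

  census <- data.frame(
    lsoa = rep(rownames(counts), times = length(ptype_levels)),
    property_type = rep(colnames(counts), each = nrow(counts)),
    n_census = as.vector(counts))
  census <- census[order(census$lsoa, census$property_type), ]
  rownames(census) <- NULL

  lookup <- merge(data.frame(uprn = props$uprn, lsoa = props$lsoa),
                  geography$hierarchy, by = "lsoa")[,
                    c("uprn", "lsoa", "ward", "lad", "region")]
  n_unmatched <- floor(cfg$unmatched_rate * nrow(lookup))
  unmatched_uprns <- character(0)
  if (n_unmatched > 0) {
    drop <- sample.int(nrow(lookup), n_unmatched)
    unmatched_uprns <- lookup$uprn[drop]
    lookup <- lookup[-drop, ]
  }
  lookup <- lookup[order(lookup$uprn), ]
  rownames(lookup) <- NULL

  setDF(props)
  lsoa_truth <- as.data.table(props)[, .(
    n_properties = .N,
    n_wood = sum(wood_final),
    n_wood_houses = sum(wood_final & property_type %in% house_types),
    n_houses = sum(property_type %in% house_types)
  ), by = lsoa]
  lsoa_truth[, prevalence_pct := 100 * n_wood_houses / n_houses]
  setorder(lsoa_truth, lsoa)
  setDF(lsoa_truth)

  list(properties = props, certificates = certificates, census = census,
       lookup = lookup,
       truth = list(lsoa = lsoa_truth,
                    n_planted_duplicates = n_dup,
                    unmatched_uprns = unmatched_uprns,
                    wood_model = cfg$wood_model))
}

#' Generate synthetic monitoring sites and hourly PM2.5
#'
#' Places urban-background monitors at the centroids of distinct urban
#' cells (plus a few non-background sites to exercise classification
#' filtering) and simulates two years of hourly PM2.5 per site: a seasonal
#' background peaking in mid-January, an optional diurnal cycle, Gaussian
#' noise, and a wood-smoke term `kappa * density` added to peak hours
#' (7pm-1am) in December-February, where `density` is the true number of
#' wood burners within the buffer radius per km2. With the default zero
#' diurnal amplitude, the winter peak/off-peak difference equals
#' `kappa * density` exactly in expectation. Values are floored at zero and
#' a fraction of hours is set missing.
#'
#' @param cfg a [scenario_config()].
#' @param geography output of [generate_geography()].
#' @param registry output of [generate_registry()] (for true burner
#'   locations).
#' @return list: `sites` (site table incl. true density),
#'   `measurements` (`site_id`, `timestamp`, `pm25`).
#' @export
generate_monitoring <- function(cfg, geography, registry) {
  set.seed(cfg$seed + 3L)
  cells <- geography$cells
  urb <- cells[geography$covariates$urban, , drop = FALSE]
  if (nrow(urb) < cfg$n_monitors)
    stop("not enough urban cells (", nrow(urb), ") for ", cfg$n_monitors,
         " monitors")
  pick <- urb[sample.int(nrow(urb), cfg$n_monitors), , drop = FALSE]
  sites <- data.frame(
    site_id = sprintf("S%03d", seq_len(cfg$n_monitors)),
    easting = pick$x0 + cfg$cell_m / 2,
    northing = pick$y0 + cfg$cell_m / 2,
    classification = "Urban Background",
    network = "AURN")
  if (cfg$n_other_sites > 0) {
    oth <- cells[sample.int(nrow(cells), cfg$n_other_sites), , drop = FALSE]
    sites <- rbind(sites, data.frame(
      site_id = sprintf("T%03d", seq_len(cfg$n_other_sites)),
      easting = oth$x0 + cfg$cell_m / 2,
      northing = oth$y0 + cfg$cell_m / 2,
      classification = "Urban Traffic",
      network = "AQE"))
  }
  pr <- registry$properties
  r <- cfg$buffer_radius_m
  area_km2 <- pi * (r / 1000)^2
  sites$true_burners_1km <- vapply(seq_len(nrow(sites)), function(i) {
    d2 <- (pr$x - sites$easting[i])^2 + (pr$y - sites$northing[i])^2
    sum(pr$wood_final[d2 <= r^2])
  }, numeric(1))
  sites$true_density <- sites$true_burners_1km / area_km2

  t0 <- as.POSIXct(paste0(min(cfg$monitor_years), "-01-01 00:00:00"),
                   tz = "UTC")
  t1 <- as.POSIXct(paste0(max(cfg$monitor_years), "-12-31 23:00:00"),
                   tz = "UTC")
  stamps <- seq(t0, t1, by = "hour")
  doy <- as.integer(format(stamps, "%j"))
  hr <- as.integer(format(stamps, "%H"))
  mth <- as.integer(format(stamps, "%m"))
  bg <- cfg$pm25_background +
    cfg$pm25_seasonal_amp * cos(2 * pi * (doy - 15) / 365.25) +
    cfg$pm25_diurnal_amp * cos(2 * pi * (hr - 20) / 24)
  peak <- (hr %in% cfg$peak_hours) & (mth %in% c(12L, 1L, 2L))
  nt <- length(stamps)
  ms <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    v <- bg + cfg$kappa * sites$true_density[i] * peak +
      stats::rnorm(nt, 0, cfg$sigma)
    v <- pmax(v, 0)
    if (cfg$missing_rate > 0)
      v[stats::runif(nt) < cfg$missing_rate] <- NA_real_
    ms[[i]] <- data.table(site_id = sites$site_id[i], timestamp = stamps,
                          pm25 = v)
  }
  measurements <- rbindlist(ms)
  setDF(measurements)
  list(sites = sites, measurements = measurements)
}

#' Generate a complete synthetic scenario
#'
#' Runs geography, registry and monitoring generation under one master
#' seed. Everything downstream of the pipeline can be exercised from this
#' object alone.
#'
#' @param cfg a [scenario_config()].
#' @param monitoring also simulate monitors and PM2.5 (default TRUE; the
#'   hourly series is the bulk of the runtime).
#' @return list with `cfg`, `geography`, `registry` and (optionally)
#'   `monitoring`.
#' @export
generate_scenario <- function(cfg = scenario_config(), monitoring = TRUE) {
  geography <- generate_geography(cfg)
  registry <- generate_registry(cfg, geography)
  out <- list(cfg = cfg, geography = geography, registry = registry)
  if (monitoring)
    out$monitoring <- generate_monitoring(cfg, geography, registry)
  class(out) <- "wb_scenario"
  out
}

register_headers <- c(certificate_id = "LMK_KEY", uprn = "UPRN",
                      inspection_date = "INSPECTION_DATE",
                      property_type_raw = "PROPERTY_TYPE",
                      built_form_raw = "BUILT_FORM",
                      tenure_raw = "TENURE",
                      transaction_type_raw = "TRANSACTION_TYPE",
                      mainheat_text = "MAINHEAT_DESCRIPTION",
                      secondheat_text = "SECONDHEAT_DESCRIPTION")

#' Write a scenario to disk in the dialects the pipeline reads
#'
#' Emits `epc.csv` (open-register headers), `census_stock.csv`,
#' `uprn_lookup.csv`, `lsoa_covariates.csv`, `boundaries.geojson`,
#' `sites.csv`, `pm25.csv` and a `manifest.yaml` recording the seed and a
#' truth summary. Writing is deterministic: the same seed produces
#' byte-identical files.
#'
#' @param scenario output of [generate_scenario()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  certs <- scenario$registry$certificates
  out <- certs
  names(out) <- register_headers[names(certs)]
  out$INSPECTION_DATE <- format(certs$inspection_date, "%Y-%m-%d")
  utils::write.csv(out, p("epc.csv"), row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(scenario$registry$census, p("census_stock.csv"),
                   row.names = FALSE)
  lk <- scenario$registry$lookup
  names(lk) <- c("UPRN", "LSOA21CD", "WD22CD", "LAD22CD", "RGN22CD")
  utils::write.csv(lk, p("uprn_lookup.csv"), row.names = FALSE)
  cov <- merge(scenario$geography$covariates,
               scenario$geography$areas, by = "lsoa")
  utils::write.csv(cov, p("lsoa_covariates.csv"), row.names = FALSE)
  write_geojson_polygons(scenario$geography$polys, p("boundaries.geojson"))
  files <- c(epc = p("epc.csv"), census = p("census_stock.csv"),
             lookup = p("uprn_lookup.csv"),
             covariates = p("lsoa_covariates.csv"),
             boundaries = p("boundaries.geojson"))
  if (!is.null(scenario$monitoring)) {
    utils::write.csv(scenario$monitoring$sites, p("sites.csv"),
                     row.names = FALSE)
    ms <- scenario$monitoring$measurements
    ms$timestamp <- format(ms$timestamp, "%Y-%m-%dT%H:%M:%S")
    data.table::fwrite(ms, p("pm25.csv"))
    files <- c(files, sites = p("sites.csv"), pm25 = p("pm25.csv"))
  }
  truth <- scenario$registry$truth
  manifest <- list(
    seed = scenario$cfg$seed,
    n_lsoas = nrow(scenario$geography$covariates),
    n_properties = nrow(scenario$registry$properties),
    n_certificates = nrow(certs),
    n_planted_duplicates = truth$n_planted_duplicates,
    n_unmatched_uprns = length(truth$unmatched_uprns),
    total_wood_burners = sum(truth$lsoa$n_wood),
    mean_prevalence_pct = mean(truth$lsoa$prevalence_pct))
  yaml::write_yaml(manifest, p("manifest.yaml"))
  files <- c(files, manifest = p("manifest.yaml"))
  invisible(files)
}
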