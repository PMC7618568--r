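#' Default run configuration
#'
#' Every analysis constant surfaces here with its standard value as the
#' default: the 20-certificate suppression threshold, 7pm-1am peak hours,
#' 5am-5pm off-peak hours, JJA/DJF seasons, 500/1000/2000 m buffer radii,
#' B = 10,000 bootstrap replications, 5th/95th percentile map truncation.
#'
#' @param input_dir directory holding the input files (the dialect written
#'   by [write_scenario()]).
#' @param outdir directory for artefacts.
#' @param ... overrides for any key.
#' @return a validated `run_config` list.
#' @export
run_config <- function(input_dir = ".", outdir = "wb_output", ...) {
  cfg <- list(
    input_dir = input_dir, outdir = outdir,
    study_window = c("2009-01-01", "2025-02-28"),
    min_epc = 20,
    fuel = "wood_fuel",
    buffer_radii = c(500, 1000, 2000),
    grid_cell = 1000,
    peak_hours = c(19:23, 0L), offpeak_hours = 5:16,
    min_hours = 24,
    B = 10000, alpha = 0.05, seed = 1L,
    truncation = c(0.05, 0.95),
    keyword_ruleset = NULL,   # path to a YAML with wood/solid keyword lists
    scenario = list(),        # scenario_config() overrides for `simulate`
    date_field = "inspection_date")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  bad <- character(0)
  if (!all(cfg$buffer_radii > 0)) bad <- c(bad, "buffer_radii must be positive")
  if (length(intersect(cfg$peak_hours, cfg$offpeak_hours)))
    bad <- c(bad, "peak_hours and offpeak_hours must be disjoint")
  if (cfg$B < 100) bad <- c(bad, "B must be at least 100")
  if (cfg$min_epc < 0) bad <- c(bad, "min_epc must be non-negative")
  if (length(bad)) stop("invalid configuration: ",
                        paste(bad, collapse = "; "))
  invisible(cfg)
}

#' Read a run configuration from YAML
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

load_ruleset <- function(cfg) {
  if (is.null(cfg$keyword_ruleset)) return(keyword_ruleset())
  y <- yaml::read_yaml(cfg$keyword_ruleset)
  keyword_ruleset(wood_keywords = y$wood, solid_keywords = y$solid)
}

log_count <- function(stage, what, n) {
  message(sprintf("[%s] %s: %d", stage, what, n))
}

in_path <- function(cfg, f) {
  p <- file.path(cfg$input_dir, f)
  if (!file.exists(p)) stop("missing input: ", p)
  p
}
out_path <- function(cfg, f) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  file.path(cfg$outdir, f)
}

stage_simulate <- function(cfg) {
  scn_args <- cfg$scenario
  scn_args$seed <- scn_args$seed %||% cfg$seed
  scenario <- generate_scenario(do.call(scenario_config, scn_args))
  files <- write_scenario(scenario, cfg$input_dir)
  log_count("simulate", "files written", length(files))
  files
}

stage_ingest <- function(cfg) {
  ruleset <- load_ruleset(cfg)
  certs <- read_epc_csv(in_path(cfg, "epc.csv"),
                        study_window = as.Date(cfg$study_window))
  log_count("ingest", "certificates read", nrow(certs))
  certs <- certs[certs$in_window, , drop = FALSE]
  log_count("ingest", "in study window", nrow(certs))
  certs <- deduplicate_certificates(certs)
  log_count("ingest", "after deduplication", nrow(certs))
  fuel <- classify_heat_source(certs$mainheat_text, certs$secondheat_text,
                               ruleset)
  certs$solid_fuel <- fuel$solid_fuel
  certs$wood_fuel <- fuel$wood_fuel
  certs$property_type <- harmonise_property_type(certs$property_type_raw,
                                                 certs$built_form_raw)
  certs$tenure <- harmonise_tenure(certs$tenure_raw,
                                   certs$transaction_type_raw)
  lookup <- utils::read.csv(in_path(cfg, "uprn_lookup.csv"),
                            colClasses = "character")
  certs <- link_geography(certs, lookup)
  certs <- flag_most_recent(certs)
  log_count("ingest", "latest certificates", sum(certs$is_latest))
  cpath <- out_path(cfg, "certificates.csv")
  utils::write.csv(certs, cpath, row.names = FALSE)
  ppath <- out_path(cfg, "properties.csv")
  utils::write.csv(certs[certs$is_latest, , drop = FALSE], ppath,
                   row.names = FALSE)
  c(certificates = cpath, properties = ppath)
}

read_stage_csv <- function(cfg, f) {
  p <- file.path(cfg$outdir, f)
  if (!file.exists(p)) stop("missing input: ", p,
                            " (run the earlier stage first)")
  out <- utils::read.csv(p)
  if ("inspection_date" %in% names(out))
    out$inspection_date <- as.Date(out$inspection_date)
  for (col in intersect(c("wood_fuel", "solid_fuel", "is_latest", "urban",
                          "sca"), names(out)))
    out[[col]] <- as.logical(out[[col]])
  out
}

stage_estimate <- function(cfg) {
  props <- read_stage_csv(cfg, "properties.csv")
  census <- utils::read.csv(in_path(cfg, "census_stock.csv"))
  cov <- utils::read.csv(in_path(cfg, "lsoa_covariates.csv"))
  rates <- stratum_rates(props, fuel = cfg$fuel, min_epc = cfg$min_epc)
  log_count("estimate", "strata", nrow(rates))
  log_count("estimate", "suppressed strata", sum(rates$suppressed))
  cc <- corrected_counts(rates, census)
  est <- area_estimates(cc, cov[c("lsoa", "area_km2")])
  hierarchy <- unique(utils::read.csv(in_path(cfg, "uprn_lookup.csv"),
                                      colClasses = "character")[
                                        c("LSOA21CD", "WD22CD", "LAD22CD",
                                          "RGN22CD")])
  names(hierarchy) <- c("lsoa", "ward", "lad", "region")
  paths <- c(lsoa = out_path(cfg, "estimates_lsoa.csv"))
  utils::write.csv(est, paths[["lsoa"]], row.names = FALSE)
  for (lv in c("ward", "lad", "region")) {
    agg <- aggregate_estimates(est, hierarchy, lv)
    paths[[lv]] <- out_path(cfg, paste0("estimates_", lv, ".csv"))
    utils::write.csv(agg, paths[[lv]], row.names = FALSE)
  }
  mp <- est
  mp$concentration_truncated <- truncate_for_mapping(
    mp$concentration_per_km2, cfg$truncation[1], cfg$truncation[2])
  paths[["map"]] <- out_path(cfg, "map_ready_lsoa.csv")
  utils::write.csv(mp[c("geography", "prevalence_pct",
                        "concentration_per_km2", "concentration_truncated",
                        "n_strata_suppressed")],
                   paths[["map"]], row.names = FALSE)
  paths
}

stage_trends <- function(cfg) {
  certs <- read_stage_csv(cfg, "certificates.csv")
  cov <- utils::read.csv(in_path(cfg, "lsoa_covariates.csv"))
  cov$urban <- as.logical(cov$urban)
  tr <- annual_prevalence(certs, cov, fuel = cfg$fuel)
  rp <- repeat_epc_prevalence(certs, fuel = cfg$fuel)
  log_count("trends", "trend cells", nrow(tr))
  paths <- c(trend = out_path(cfg, "trend_annual.csv"),
             repeat_epc = out_path(cfg, "trend_repeat_epc.csv"))
  utils::write.csv(tr, paths[["trend"]], row.names = FALSE)
  utils::write.csv(rp, paths[["repeat_epc"]], row.names = FALSE)
  paths
}

stage_validate <- function(cfg) {
  est <- utils::read.csv(file.path(cfg$outdir, "estimates_lsoa.csv"))
  polys <- read_geojson_polygons(in_path(cfg, "boundaries.geojson"))
  sites <- utils::read.csv(in_path(cfg, "sites.csv"))
  ms <- data.table::fread(in_path(cfg, "pm25.csv"), data.table = FALSE)
  sites <- sites[sites$classification == "Urban Background", , drop = FALSE]
  log_count("validate", "urban background sites", nrow(sites))
  values <- stats::setNames(est$est_count, est$geography)
  houses <- stats::setNames(est$house_epc, est$geography)
  expo <- sites["site_id"]
  for (r in cfg$buffer_radii) {
    expo[[paste0("burners_", r, "m")]] <- vapply(seq_len(nrow(sites)),
      function(i) buffer_count(polys, values,
                               c(sites$easting[i], sites$northing[i]), r),
      numeric(1))
  }
  expo$burners_gridsquare <- vapply(seq_len(nrow(sites)), function(i)
    grid_count(polys, values, c(sites$easting[i], sites$northing[i]),
               cell = cfg$grid_cell), numeric(1))
  expo$houses_1km <- vapply(seq_len(nrow(sites)), function(i)
    buffer_count(polys, houses, c(sites$easting[i], sites$northing[i]),
                 1000), numeric(1))
  paths <- c(exposure = out_path(cfg, "site_exposure.csv"))
  utils::write.csv(expo, paths[["exposure"]], row.names = FALSE)

  main_x <- expo[[paste0("burners_", cfg$buffer_radii[
    which.min(abs(cfg$buffer_radii - 1000))], "m")]]
  exposure <- data.frame(site_id = expo$site_id, x = main_x)
  corr <- validation_correlations(exposure, ms, B = cfg$B,
                                  alpha = cfg$alpha, seed = cfg$seed,
                                  min_hours = cfg$min_hours)
  corr$exposure <- "burners_buffer"
  ctrl <- validation_correlations(
    data.frame(site_id = expo$site_id, x = expo$houses_1km), ms,
    B = cfg$B, alpha = cfg$alpha, seed = cfg$seed,
    min_hours = cfg$min_hours)
  ctrl$exposure <- "housing_density"
  corr <- rbind(corr, ctrl)
  paths[["correlations"]] <- out_path(cfg, "correlations.csv")
  utils::write.csv(corr, paths[["correlations"]], row.names = FALSE)

  # paired winter-summer difference for the peak statistic, per day type
  sd_rows <- list()
  scatter <- list()
  for (dtp in c("weekday", "weekend")) {
    w <- peak_offpeak_diff(ms, "winter", dtp, cfg$peak_hours,
                           cfg$offpeak_hours, cfg$min_hours)
    s <- peak_offpeak_diff(ms, "summer", dtp, cfg$peak_hours,
                           cfg$offpeak_hours, cfg$min_hours)
    d <- merge(merge(exposure, w[c("site_id", "peak_diff")], by = "site_id"),
               s[c("site_id", "peak_diff")], by = "site_id",
               suffixes = c("_winter", "_summer"))
    ci <- season_difference_ci(d, "x", "peak_diff_winter",
                               "peak_diff_summer", B = cfg$B,
                               alpha = cfg$alpha, seed = cfg$seed)
    sd_rows[[dtp]] <- data.frame(
      daytype = dtp, diff = attr(ci, "estimate"),
      r_winter = attr(ci, "r_winter"), r_summer = attr(ci, "r_summer"),
      ci_low = ci[1], ci_high = ci[2], n_sites = nrow(d), B = cfg$B)
    for (season in c("winter", "summer")) {
      pd <- if (season == "winter") w else s
      scatter[[paste(dtp, season)]] <- data.frame(
        site_id = pd$site_id, season = season, daytype = dtp,
        log_burners = log(exposure$x[match(pd$site_id,
                                           exposure$site_id)] + 1),
        peak_diff = pd$peak_diff, mean_pm25 = pd$mean_pm25)
    }
  }
  paths[["season_difference"]] <- out_path(cfg, "season_difference.csv")
  utils::write.csv(do.call(rbind, sd_rows), paths[["season_difference"]],
                   row.names = FALSE)
  paths[["scatter"]] <- out_path(cfg, "scatter_data.csv")
  utils::write.csv(do.call(rbind, scatter), paths[["scatter"]],
                   row.names = FALSE)
  paths
}

stage_associate <- function(cfg) {
  est <- utils::read.csv(file.path(cfg$outdir, "estimates_lsoa.csv"))
  cov <- utils::read.csv(in_path(cfg, "lsoa_covariates.csv"))
  cov$urban <- as.logical(cov$urban)
  cov$sca <- as.logical(cov$sca)
  d <- merge(est[c("geography", "prevalence_pct")], cov,
             by.x = "geography", by.y = "lsoa")
  names(d)[1] <- "lsoa"
  d <- d[stats::complete.cases(d[c("prevalence_pct", "imd_score",
                                   "median_age", "pct_white")]), ]
  d$prevalence <- squeeze_proportions(d$prevalence_pct / 100)
  fits <- stratified_models(d)
  tab <- do.call(rbind, Map(tidy_beta_fit, fits, names(fits)))
  paths <- c(models = out_path(cfg, "beta_models.csv"))
  utils::write.csv(tab, paths[["models"]], row.names = FALSE)
  t2 <- prevalence_decile_table(d)
  paths[["decile_table"]] <- out_path(cfg, "prevalence_deciles.csv")
  utils::write.csv(t2, paths[["decile_table"]], row.names = FALSE)
  f4 <- rbind(cbind(covariate = "imd_score",
                    region_decile_points(d, "imd_score")),
              cbind(covariate = "pct_white",
                    region_decile_points(d, "pct_white")))
  paths[["region_deciles"]] <- out_path(cfg, "region_decile_points.csv")
  utils::write.csv(f4, paths[["region_deciles"]], row.names = FALSE)
  paths
}

stage_report <- function(cfg) {
  props <- read_stage_csv(cfg, "properties.csv")
  cov <- utils::read.csv(in_path(cfg, "lsoa_covariates.csv"))
  cov$urban <- as.logical(cov$urban)
  cov$sca <- as.logical(cov$sca)
  idx <- match(props$lsoa, cov$lsoa)
  props$urban <- cov$urban[idx]
  props$sca <- cov$sca[idx]
  t1 <- summarise_by_flag(props)
  paths <- c(table1 = out_path(cfg, "table1_characteristics.csv"))
  utils::write.csv(t1, paths[["table1"]], row.names = FALSE)
  paths
}

#' Run the pipeline
#'
#' Orchestrates the stages end-to-end. Each stage reads its declared
#' inputs, writes its artefacts under `cfg$outdir` and logs row counts at
#' every filter; re-running a stage with unchanged inputs reproduces its
#' outputs.
#'
#' @param subcommand one of `"simulate"`, `"ingest"`, `"estimate"`,
#'   `"trends"`, `"validate"`, `"associate"`, `"report"`, `"all"`.
#' @param cfg a [run_config()] (or path to a YAML config).
#' @return invisibly, a named vector of artefact paths.
#' @export
run_pipeline <- function(subcommand = "all", cfg = run_config()) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  validate_run_config(cfg)
  subcommand <- match.arg(subcommand,
                          c("all", "simulate", "ingest", "estimate",
                            "trends", "validate", "associate", "report"))
  stages <- if (subcommand == "all")
    c("simulate", "ingest", "estimate", "trends", "validate", "associate",
      "report")
  else subcommand
  paths <- character(0)
  for (st in stages) {
    fn <- switch(st, simulate = stage_simulate, ingest = stage_ingest,
                 estimate = stage_estimate, trends = stage_trends,
                 validate = stage_validate, associate = stage_associate,
                 report = stage_report)
    paths <- c(paths, fn(cfg))
  }
  invisible(paths)
}
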