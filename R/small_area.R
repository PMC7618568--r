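#' @keywords internal
house_types <- c("detached", "semi_detached", "terrace")

#' Per-stratum EPC fuel rates with small-sample suppression
#'
#' Computes the observed wood/solid-fuel rate within each LSOA x
#' property-type stratum from the latest-certificate property set. Strata
#' with fewer than `min_epc` certificates carry too much sampling noise and
#' are suppressed: their rate is reported but flagged, and downstream
#' corrected counts exclude them from both numerator and denominator.
#'
#' @param properties data.frame with `lsoa`, `property_type` and the fuel
#'   flag column; if an `is_latest` column is present only latest
#'   certificates are used.
#' @param fuel name of the logical fuel-flag column (default `wood_fuel`).
#' @param min_epc suppression threshold (default 20 certificates).
#' @return data.frame with columns `lsoa`, `property_type`, `n_epc`,
#'   `n_fuel`, `p_hat`, `suppressed`.
#' @export
stratum_rates <- function(properties, fuel = "wood_fuel", min_epc = 20) {
  stopifnot(all(c("lsoa", "property_type", fuel) %in% names(properties)))
  if ("is_latest" %in% names(properties))
    properties <- properties[properties$is_latest %in% TRUE, , drop = FALSE]
  dt <- as.data.table(properties)
  dt[, property_type := as.character(property_type)]
  out <- dt[!is.na(lsoa),
            .(n_epc = .N, n_fuel = sum(get(fuel) %in% TRUE)),
            by = .(lsoa, property_type)]
  out[, p_hat := n_fuel / n_epc]
  out[, suppressed := n_epc < min_epc]
  setorder(out, lsoa, property_type)
  setDF(out)
  out
}

#' Census-corrected burner counts by stratum
#'
#' Post-stratification: the estimated number of fuel-flagged properties in a
#' stratum is the EPC rate multiplied by the Census count of properties in
#' that stratum, `est = p_hat * n_census`. Suppressed strata contribute
#' `NA` (excluded downstream from numerator and denominator); optionally
#' their rate can be borrowed from the pooled local-authority rate instead.
#' Census strata with no EPC coverage are suppressed. An unsuppressed
#' stratum missing from the Census stock triggers a warning and is treated
#' as suppressed.
#'
#' @param rates output of [stratum_rates()].
#' @param stock data.frame `lsoa`, `property_type`, `n_census`.
#' @param suppressed_action `"exclude"` (default) or `"borrow"` — replace a
#'   suppressed stratum's rate by the pooled LAD-level rate for that
#'   property type.
#' @param hierarchy required for `"borrow"`: data.frame `lsoa`, `lad`.
#' @return data.frame `lsoa`, `property_type`, `n_census`, `n_epc`,
#'   `n_fuel`, `p_hat`, `suppressed`, `est_count` (`NA` when suppressed and
#'   not borrowed).
#' @export
corrected_counts <- function(rates, stock,
                             suppressed_action = c("exclude", "borrow"),
                             hierarchy = NULL) {
  suppressed_action <- match.arg(suppressed_action)
  stopifnot(all(c("lsoa", "property_type", "n_census") %in% names(stock)))
  r <- as.data.table(rates)
  s <- as.data.table(stock)[, .(lsoa, property_type = as.character(property_type),
                                n_census = as.numeric(n_census))]
  m <- merge(s, r, by = c("lsoa", "property_type"), all = TRUE)
  no_stock <- is.na(m$n_census)
  if (any(no_stock & !m$suppressed %in% TRUE)) {
    warning(sum(no_stock & !m$suppressed %in% TRUE),
            " unsuppressed stratum(s) missing from Census stock; treated",
            " as suppressed")
  }
  m[is.na(suppressed), `:=`(suppressed = TRUE, n_epc = 0L, n_fuel = 0L)]
  m[no_stock, suppressed := TRUE]
  m[, est_count := fifelse(suppressed, NA_real_, p_hat * n_census)]
  if (suppressed_action == "borrow") {
    if (is.null(hierarchy) || !all(c("lsoa", "lad") %in% names(hierarchy)))
      stop("suppressed_action = 'borrow' needs a hierarchy with lsoa and lad")
    h <- as.data.table(hierarchy)[, .(lsoa, lad)]
    m <- merge(m, h, by = "lsoa", all.x = TRUE)
    pool <- m[, .(p_lad = sum(n_fuel, na.rm = TRUE) /
                    pmax(sum(n_epc, na.rm = TRUE), 1L)),
              by = .(lad, property_type)]
    m <- merge(m, pool, by = c("lad", "property_type"), all.x = TRUE)
    m[suppressed & !is.na(n_census) & !is.na(p_lad),
      est_count := p_lad * n_census]
    m[, c("lad", "p_lad") := NULL]
  }
  setorder(m, lsoa, property_type)
  setDF(m)
  m
}

#' Area prevalence from corrected stratum counts
#'
#' Prevalence is defined over houses only (detached, semi-detached,
#' terrace): flats and other accommodation rarely accommodate a burner.
#' `100 * sum(est_count) / sum(n_census)` over unsuppressed house strata;
#' `NA` (with a reason attribute) if all house strata are suppressed or the
#' denominator is zero.
#'
#' @param est_counts data.frame as from [corrected_counts()] (one
#'   geography's strata).
#' @return prevalence percentage in `[0, 100]` or `NA`.
#' @export
area_prevalence <- function(est_counts) {
  h <- est_counts[est_counts$property_type %in% house_types &
                    !est_counts$suppressed %in% TRUE, , drop = FALSE]
  h <- h[!is.na(h$est_count), , drop = FALSE]
  denom <- sum(h$n_census)
  if (!nrow(h) || denom <= 0)
    return(structure(NA_real_, reason = "all house strata suppressed or zero stock"))
  100 * sum(h$est_count) / denom
}

#' Area concentration of burners per square kilometre
#'
#' Unlike prevalence, concentration is defined relative to land area rather
#' than a housing denominator, so every property type contributes
#' (including flats). `sum(est_count) / area_km2` over unsuppressed strata.
#'
#' @param est_counts data.frame as from [corrected_counts()] (one
#'   geography's strata).
#' @param area_km2 positive area in square kilometres.
#' @return burners per km2.
#' @export
area_concentration <- function(est_counts, area_km2) {
  if (!is.finite(area_km2) || area_km2 <= 0)
    stop("area_km2 must be positive")
  sum(est_counts$est_count[!est_counts$suppressed %in% TRUE], na.rm = TRUE) /
    area_km2
}

#' Per-geography estimate table
#'
#' Combines corrected stratum counts and areas into one row per geography:
#' estimated burner count (all property types), prevalence (houses only,
#' corrected and uncorrected), concentration per km2 and suppression
#' metadata. Numerator/denominator columns are retained so estimates remain
#' exactly aggregable with [aggregate_estimates()].
#'
#' @param est_counts output of [corrected_counts()].
#' @param areas data.frame `lsoa`, `area_km2`.
#' @return data.frame keyed by `geography` (the LSOA code), `level =
#'   "lsoa"`, with `est_count`, `house_est`, `house_census`, `house_epc`,
#'   `house_fuel`, `prevalence_pct`, `prevalence_uncorrected_pct`,
#'   `area_km2`, `concentration_per_km2`, `n_strata_suppressed`.
#' @export
area_estimates <- function(est_counts, areas) {
  stopifnot(all(c("lsoa", "area_km2") %in% names(areas)))
  dt <- as.data.table(est_counts)
  dt[, is_house := property_type %in% house_types]
  agg <- dt[, .(
    est_count = sum(est_count[!suppressed], na.rm = TRUE),
    house_est = sum(est_count[!suppressed & is_house], na.rm = TRUE),
    house_census = sum(n_census[!suppressed & is_house], na.rm = TRUE),
    house_epc = sum(n_epc[!suppressed & is_house], na.rm = TRUE),
    house_fuel = sum(n_fuel[!suppressed & is_house], na.rm = TRUE),
    n_strata_suppressed = sum(suppressed)
  ), by = lsoa]
  agg <- merge(agg, as.data.table(areas)[, .(lsoa, area_km2 = as.numeric(area_km2))],
               by = "lsoa", all.x = TRUE)
  if (any(!is.finite(agg$area_km2) | agg$area_km2 <= 0))
    stop("non-positive or missing area for: ",
         paste(utils::head(agg$lsoa[!is.finite(agg$area_km2) |
                                      agg$area_km2 <= 0], 5), collapse = ", "))
  agg[, prevalence_pct := fifelse(house_census > 0,
                                  100 * house_est / house_census, NA_real_)]
  agg[, prevalence_uncorrected_pct := fifelse(house_epc > 0,
                                              100 * house_fuel / house_epc,
                                              NA_real_)]
  agg[, concentration_per_km2 := est_count / area_km2]
  setnames(agg, "lsoa", "geography")
  agg[, level := "lsoa"]
  setcolorder(agg, c("geography", "level"))
  setDF(agg)
  agg
}

#' Aggregate LSOA estimates up the geographic hierarchy
#'
#' Parent counts are sums of child counts; parent prevalence is the
#' count-weighted ratio of summed numerators to summed denominators; parent
#' area is the sum of child areas. Every LSOA must map to exactly one
#' parent: orphans are an error.
#'
#' @param lsoa_estimates output of [area_estimates()].
#' @param hierarchy data.frame `lsoa`, `ward`, `lad`, `region`.
#' @param level one of `"ward"`, `"lad"`, `"region"`.
#' @return estimate table at the requested level (same columns).
#' @export
aggregate_estimates <- function(lsoa_estimates, hierarchy,
                                level = c("ward", "lad", "region")) {
  level <- match.arg(level)
  stopifnot(all(c("lsoa", level) %in% names(hierarchy)))
  dt <- as.data.table(lsoa_estimates)
  idx <- match(dt$geography, hierarchy$lsoa)
  if (anyNA(idx))
    stop("LSOA(s) missing from hierarchy: ",
         paste(utils::head(dt$geography[is.na(idx)], 10), collapse = ", "))
  set(dt, j = "parent", value = hierarchy[[level]][idx])
  agg <- dt[, .(
    est_count = sum(est_count),
    house_est = sum(house_est),
    house_census = sum(house_census),
    house_epc = sum(house_epc),
    house_fuel = sum(house_fuel),
    n_strata_suppressed = sum(n_strata_suppressed),
    area_km2 = sum(area_km2)
  ), by = parent]
  agg[, prevalence_pct := fifelse(house_census > 0,
                                  100 * house_est / house_census, NA_real_)]
  agg[, prevalence_uncorrected_pct := fifelse(house_epc > 0,
                                              100 * house_fuel / house_epc,
                                              NA_real_)]
  agg[, concentration_per_km2 := est_count / area_km2]
  setnames(agg, "parent", "geography")
  set(agg, j = "level", value = level)
  setcolorder(agg, c("geography", "level"))
  setorder(agg, geography)
  setDF(agg)
  agg
}

#' Truncate extreme values for choropleth mapping
#'
#' Clips a vector to its 5th and 95th percentiles (linear interpolation
#' between order statistics) so a handful of extreme areas do not dominate
#' the map colour scale. `NA`s pass through.
#'
#' @param values numeric vector with at least two finite values.
#' @param lower,upper percentile probabilities (defaults 0.05 and 0.95).
#' @return the clipped vector.
#' @export
truncate_for_mapping <- function(values, lower = 0.05, upper = 0.95) {
  fin <- values[is.finite(values)]
  if (length(fin) < 2) stop("need at least two finite values")
  q <- stats::quantile(fin, c(lower, upper), names = FALSE, type = 7)
  pmin(pmax(values, q[1]), q[2])
}
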