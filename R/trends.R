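#' Deprivation deciles within urban and rural strata
#'
#' Assigns each LSOA an IMD decile computed separately within the urban and
#' rural subsets, so decile 1 is the most deprived 10% of *urban* LSOAs in
#' the urban panel and of *rural* LSOAs in the rural panel. Higher IMD
#' score means more deprived, so decile 1 holds the highest scores. Ties at
#' decile boundaries are broken by LSOA code order for determinism.
#'
#' @param covariates data.frame with `lsoa`, `imd_score`, `urban` (logical).
#' @return the input with an integer `imd_decile` column (1 = most
#'   deprived).
#' @export
imd_deciles <- function(covariates) {
  stopifnot(all(c("lsoa", "imd_score", "urban") %in% names(covariates)))
  dt <- as.data.table(covariates)
  dt[, imd_decile := {
    ord <- order(-imd_score, lsoa)
    r <- integer(.N); r[ord] <- seq_len(.N)
    as.integer(ceiling(r * 10 / .N))
  }, by = urban]
  setDF(dt)
  dt
}

#' Annual wood-burner prevalence in newly issued certificates
#'
#' For each year and stratum, the percentage of certificates issued that
#' year flagging a wood (or solid) fuel heat source. All certificates are
#' used — including repeat certificates for the same property — because a
#' property's fuel status can change between certificates. The analysis is
#' restricted to houses (detached, semi-detached, terrace); IMD deciles are
#' computed within urban/rural strata via [imd_deciles()].
#'
#' @param certificates classified, geography-linked certificate data.frame
#'   with `inspection_date`, `property_type`, `lsoa` and the fuel flag.
#' @param covariates LSOA covariates (`lsoa`, `imd_score`, `urban`,
#'   optionally `region`), used to attach deciles and urban status.
#' @param by stratification variables among `"property_type"`,
#'   `"imd_decile"`, `"urban"`, `"region"`; `"year"` is always included.
#' @param fuel fuel-flag column, default `"wood_fuel"`.
#' @param house_only restrict to house property types (default TRUE).
#' @return data.frame of trend cells with `n_epcs` and `prevalence_pct`;
#'   empty strata are omitted.
#' @export
annual_prevalence <- function(certificates, covariates = NULL,
                              by = c("property_type", "imd_decile", "urban"),
                              fuel = "wood_fuel", house_only = TRUE) {
  stopifnot(all(c("inspection_date", "property_type", fuel) %in%
                  names(certificates)))
  dt <- as.data.table(certificates)
  dt <- dt[!is.na(inspection_date)]
  dt[, property_type := as.character(property_type)]
  if (house_only) dt <- dt[property_type %in% house_types]
  dt[, year := as.integer(format(inspection_date, "%Y"))]
  if (!is.null(covariates)) {
    cov <- as.data.table(imd_deciles(covariates))
    keep <- intersect(c("lsoa", "imd_decile", "urban", "region"), names(cov))
    dt <- merge(dt, cov[, ..keep], by = "lsoa", all.x = TRUE)
  }
  by <- intersect(by, names(dt))
  grp <- unique(c("year", by))
  out <- dt[, .(n_epcs = .N,
                prevalence_pct = 100 * mean(get(fuel) %in% TRUE)),
            by = grp]
  setorderv(out, grp)
  setDF(out)
  out
}

#' Wood-burner prevalence by certificate order for repeat-EPC properties
#'
#' Restricted to properties with multiple certificates, reports the
#' prevalence of the fuel flag at the first, second, ... certificate within
#' groups defined by the property's total number of certificates. Groups
#' with five or more certificates are excluded (small samples). Certificate
#' order follows inspection date, ties broken by certificate id (matching
#' the latest-certificate rule). Property type is taken from the property's
#' most recent certificate.
#'
#' @param certificates data.frame with `uprn`, `inspection_date`,
#'   `certificate_id`, `property_type` and the fuel flag.
#' @param fuel fuel-flag column, default `"wood_fuel"`.
#' @param max_certs largest group retained (default 4).
#' @param by_type stratify by property type (default TRUE).
#' @return data.frame `n_certs_group`, `epc_order`, (`property_type`,)
#'   `n_properties`, `prevalence_pct`.
#' @export
repeat_epc_prevalence <- function(certificates, fuel = "wood_fuel",
                                  max_certs = 4, by_type = TRUE) {
  need <- c("uprn", "inspection_date", "certificate_id", fuel)
  stopifnot(all(need %in% names(certificates)))
  dt <- as.data.table(certificates)
  dt <- dt[!is.na(uprn) & uprn != "" & !is.na(inspection_date)]
  setorder(dt, uprn, inspection_date, certificate_id)
  dt[, `:=`(epc_order = seq_len(.N), n_certs_group = .N), by = uprn]
  dt <- dt[n_certs_group >= 2 & n_certs_group <= max_certs]
  if (by_type && "property_type" %in% names(dt)) {
    dt[, property_type := as.character(property_type)[.N], by = uprn]
    grp <- c("n_certs_group", "epc_order", "property_type")
  } else grp <- c("n_certs_group", "epc_order")
  out <- dt[, .(n_properties = .N,
                prevalence_pct = 100 * mean(get(fuel) %in% TRUE)),
            by = grp]
  setorderv(out, grp)
  setDF(out)
  out
}
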