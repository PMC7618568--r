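#' Default keyword ruleset for heat-source classification
#'
#' Heat sources appear in EPCs as free text (e.g. "Room heaters, wood logs").
#' Classification is case-insensitive substring matching against two keyword
#' lists: `wood_keywords` flags wood-fuel heat sources and `solid_keywords`
#' flags solid fuel generally. Wood fuel is a subset of solid fuel, so the
#' solid list always contains the wood list; the constructor enforces this.
#' The shipped defaults are deliberately configurable data, not code: pass a
#' different ruleset (e.g. read from YAML) to reproduce a register's exact
#' vocabulary.
#'
#' @param wood_keywords character vector of lowercase substrings identifying
#'   wood fuel.
#' @param solid_keywords character vector of lowercase substrings identifying
#'   solid fuel; the wood keywords are added automatically.
#' @param fields_searched which text fields are searched.
#' @return an object of class `keyword_ruleset`.
#' @export
keyword_ruleset <- function(wood_keywords = c("wood", "log", "logs",
                                              "biomass", "pellet",
                                              "wood chip"),
                            solid_keywords = c("solid fuel", "coal",
                                               "anthracite", "smokeless",
                                               "multi-fuel", "multifuel",
                                               "peat"),
                            fields_searched = c("mainheat", "secondheat")) {
  wood <- unique(tolower(trimws(wood_keywords)))
  solid <- unique(c(wood, tolower(trimws(solid_keywords))))
  structure(
    list(wood_keywords = wood, solid_keywords = solid,
         fields_searched = match.arg(fields_searched,
                                     c("mainheat", "secondheat"),
                                     several.ok = TRUE)),
    class = "keyword_ruleset"
  )
}

#' @export
print.keyword_ruleset <- function(x, ...) {
  cat("<keyword_ruleset>\n")
  cat("  wood: ", paste(x$wood_keywords, collapse = ", "), "\n", sep = "")
  cat("  solid:", paste(x$solid_keywords, collapse = ", "), "\n")
  cat("  fields:", paste(x$fields_searched, collapse = ", "), "\n")
  invisible(x)
}

#' Classify free-text heat-source descriptions
#'
#' Flags solid-fuel and wood-fuel heat sources from the main and secondary
#' heat-source description fields by case-insensitive fixed substring
#' matching. A property is wood-fuelled if any wood keyword occurs in either
#' searched field; solid-fuelled if any solid keyword occurs. Because the
#' wood keywords are a subset of the solid keywords, `wood_fuel` implies
#' `solid_fuel`. Empty or missing text yields `FALSE` for both flags.
#'
#' @param mainheat_text,secondheat_text character vectors (recycled to a
#'   common length).
#' @param ruleset a [keyword_ruleset()].
#' @return a data.frame with logical columns `solid_fuel` and `wood_fuel`.
#' @examples
#' classify_heat_source("Boiler and radiators, mains gas",
#'                      "Room heaters, wood logs")
#' @export
classify_heat_source <- function(mainheat_text, secondheat_text = "",
                                 ruleset = keyword_ruleset()) {
  n <- max(length(mainheat_text), length(secondheat_text))
  main <- rep_len(as.character(mainheat_text), n)
  second <- rep_len(as.character(secondheat_text), n)
  main[is.na(main)] <- ""
  second[is.na(second)] <- ""
  txt <- character(n)
  if ("mainheat" %in% ruleset$fields_searched) txt <- main
  if ("secondheat" %in% ruleset$fields_searched)
    txt <- paste(txt, second, sep = " | ")
  txt <- tolower(txt)
  match_any <- function(keys) {
    hit <- rep(FALSE, n)
    for (k in keys) hit <- hit | grepl(k, txt, fixed = TRUE)
    hit
  }
  wood <- match_any(ruleset$wood_keywords)
  solid <- match_any(ruleset$solid_keywords) | wood
  data.frame(solid_fuel = solid, wood_fuel = wood)
}

#' Read an EPC-like certificate table
#'
#' Reads a CSV in the open-register dialect. Column names are configurable;
#' the defaults follow the England/Wales open register headers. Inspection
#' dates are parsed as `Date`; rows whose date falls outside the study
#' window keep their data but are flagged `in_window = FALSE`.
#'
#' @param path CSV path.
#' @param columns named character vector mapping internal names to file
#'   headers.
#' @param study_window length-2 `Date` (or coercible) vector; default
#'   2009-01-01 to 2025-02-28.
#' @return a data.frame of raw certificate records with standardised names:
#'   `certificate_id`, `uprn`, `inspection_date`, `property_type_raw`,
#'   `built_form_raw`, `tenure_raw`, `transaction_type_raw`,
#'   `mainheat_text`, `secondheat_text`, `in_window`.
#' @export
read_epc_csv <- function(path,
                         columns = c(certificate_id = "LMK_KEY",
                                     uprn = "UPRN",
                                     inspection_date = "INSPECTION_DATE",
                                     property_type_raw = "PROPERTY_TYPE",
                                     built_form_raw = "BUILT_FORM",
                                     tenure_raw = "TENURE",
                                     transaction_type_raw = "TRANSACTION_TYPE",
                                     mainheat_text = "MAINHEAT_DESCRIPTION",
                                     secondheat_text = "SECONDHEAT_DESCRIPTION"),
                         study_window = as.Date(c("2009-01-01",
                                                  "2025-02-28"))) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, encoding = "UTF-8")
  missing_cols <- setdiff(unname(columns), names(raw))
  if (length(missing_cols))
    stop("missing columns in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  out <- raw[unname(columns)]
  names(out) <- names(columns)
  out$inspection_date <- as.Date(out$inspection_date)
  win <- as.Date(study_window)
  out$in_window <- !is.na(out$inspection_date) &
    out$inspection_date >= win[1] & out$inspection_date <= win[2]
  out
}

squish <- function(x) gsub("\\s+", " ", trimws(as.character(x)))

#' Remove duplicated certificates
#'
#' Removes byte-identical duplicate rows (after whitespace normalisation of
#' character fields) and resolves certificate-id collisions with differing
#' fields by keeping the record with the later inspection date. Records with
#' a missing certificate id cannot be deduplicated and are rejected.
#'
#' @param records data.frame of certificate records (as from
#'   [read_epc_csv()]).
#' @return the deduplicated data.frame, with attributes `n_removed`
#'   (duplicates dropped), `n_rejected` (missing certificate id) and
#'   `rejected` (the rejected rows, with a `reason` column).
#' @export
deduplicate_certificates <- function(records) {
  stopifnot(is.data.frame(records), "certificate_id" %in% names(records))
  chr <- vapply(records, is.character, logical(1))
  records[chr] <- lapply(records[chr], squish)
  bad <- is.na(records$certificate_id) | records$certificate_id == ""
  rejected <- records[bad, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- "missing certificate_id"
  records <- records[!bad, , drop = FALSE]
  n0 <- nrow(records)

  # exact duplicates first, then id collisions resolved by latest date
  records <- records[!duplicated(records), , drop = FALSE]
  if (anyDuplicated(records$certificate_id)) {
    ord <- order(records$certificate_id,
                 records$inspection_date,
                 decreasing = c(FALSE, TRUE), method = "radix")
    records <- records[ord, , drop = FALSE]
    records <- records[!duplicated(records$certificate_id), , drop = FALSE]
  }
  rownames(records) <- NULL
  structure(records,
            n_removed = n0 - nrow(records),
            n_rejected = nrow(rejected),
            rejected = rejected)
}

#' Flag each property's most recent certificate
#'
#' Within each UPRN the certificate with the latest inspection date is
#' flagged `is_latest = TRUE`; date ties are broken deterministically by the
#' lexicographically greatest certificate id. Records with an unparseable
#' date, or no UPRN, cannot compete and are flagged `FALSE` (with a warning
#' when dates are missing).
#'
#' @param records deduplicated certificate data.frame with `uprn`,
#'   `inspection_date`, `certificate_id`.
#' @return the data.frame with a logical `is_latest` column and an
#'   `n_certificates` column (certificates per UPRN among datable records).
#' @export
flag_most_recent <- function(records) {
  stopifnot(all(c("uprn", "inspection_date", "certificate_id") %in%
                  names(records)))
  dt <- as.data.table(records)
  no_uprn <- is.na(dt$uprn) | dt$uprn == ""
  no_date <- is.na(dt$inspection_date)
  if (any(no_date & !no_uprn))
    warning(sum(no_date & !no_uprn),
            " record(s) with unparseable inspection date excluded from",
            " latest-certificate flagging")
  dt[, is_latest := FALSE]
  dt[, n_certificates := 0L]
  eligible <- which(!no_uprn & !no_date)
  if (length(eligible)) {
    el <- dt[eligible, .(uprn, inspection_date, certificate_id)]
    el[, row0 := eligible]
    # winner per uprn: max date, ties broken by greatest certificate_id
    setorder(el, uprn, -inspection_date, -certificate_id)
    win <- el[, .(row0 = row0[1], n = .N), by = uprn]
    dt[win$row0, is_latest := TRUE]
    dt[eligible, n_certificates := win$n[match(dt$uprn[eligible], win$uprn)]]
  }
  setDF(dt)
  dt
}

#' Harmonise property type to Census categories
#'
#' Maps the register's `PROPERTY_TYPE` x `BUILT_FORM` pair onto the 2021
#' Census accommodation categories. Houses and bungalows are split by built
#' form into detached / semi-detached / terrace; flats and maisonettes map
#' to flat; everything unseen maps to `other`.
#'
#' @param property_type_raw,built_form_raw character vectors.
#' @return factor with levels detached, semi_detached, terrace, flat, other.
#' @export
harmonise_property_type <- function(property_type_raw, built_form_raw = "") {
  n <- max(length(property_type_raw), length(built_form_raw))
  pt <- tolower(squish(rep_len(as.character(property_type_raw), n)))
  bf <- tolower(squish(rep_len(as.character(built_form_raw), n)))
  pt[is.na(pt)] <- ""
  bf[is.na(bf)] <- ""
  out <- rep("other", n)
  house <- pt %in% c("house", "bungalow")
  out[house & bf == "detached"] <- "detached"
  out[house & bf == "semi-detached"] <- "semi_detached"
  out[house & bf %in% c("mid-terrace", "end-terrace",
                        "enclosed mid-terrace",
                        "enclosed end-terrace")] <- "terrace"
  out[pt %in% c("flat", "maisonette")] <- "flat"
  factor(out, levels = c("detached", "semi_detached", "terrace",
                         "flat", "other"))
}

#' Harmonise tenure to Census categories
#'
#' A transaction type containing "new dwelling" marks a new build; otherwise
#' tenure text is mapped onto owner-occupied / privately rented / socially
#' rented. Unmapped values become `missing`.
#'
#' @param tenure_raw,transaction_type_raw character vectors.
#' @return factor with levels new_build, owner_occupied, rented_private,
#'   rented_social, missing.
#' @export
harmonise_tenure <- function(tenure_raw, transaction_type_raw = "") {
  n <- max(length(tenure_raw), length(transaction_type_raw))
  tn <- tolower(squish(rep_len(as.character(tenure_raw), n)))
  tt <- tolower(squish(rep_len(as.character(transaction_type_raw), n)))
  tn[is.na(tn)] <- ""
  tt[is.na(tt)] <- ""
  out <- rep("missing", n)
  out[grepl("owner-occupied", tn, fixed = TRUE)] <- "owner_occupied"
  out[grepl("rented (private)", tn, fixed = TRUE)] <- "rented_private"
  out[grepl("rented (social)", tn, fixed = TRUE)] <- "rented_social"
  out[grepl("new dwelling", tt, fixed = TRUE)] <- "new_build"
  factor(out, levels = c("new_build", "owner_occupied", "rented_private",
                         "rented_social", "missing"))
}

#' Link certificates to the geographic hierarchy
#'
#' Attaches LSOA, ward, local-authority and region codes via a UPRN lookup.
#' The lookup must be a function of UPRN: duplicated UPRNs are a hard error.
#' Unmatched records are retained with `NA` codes and counted.
#'
#' @param records certificate data.frame with a `uprn` column.
#' @param lookup data.frame with columns `uprn`, `lsoa`, `ward`, `lad`,
#'   `region` (open-register style headers `UPRN`, `LSOA21CD`, `WD22CD`,
#'   `LAD22CD`, `RGN22CD` are also accepted).
#' @return records with the four code columns; attribute `n_unmatched`
#'   counts records without a lookup entry.
#' @export
link_geography <- function(records, lookup) {
  alias <- c(UPRN = "uprn", LSOA21CD = "lsoa", WD22CD = "ward",
             LAD22CD = "lad", RGN22CD = "region")
  hit <- names(lookup) %in% names(alias)
  names(lookup)[hit] <- alias[names(lookup)[hit]]
  need <- c("uprn", "lsoa", "ward", "lad", "region")
  if (!all(need %in% names(lookup)))
    stop("lookup must provide columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(lookup$uprn))
    stop("duplicate UPRN in geography lookup: lookup must be a function of UPRN")
  idx <- match(records$uprn, lookup$uprn)
  for (col in c("lsoa", "ward", "lad", "region"))
    records[[col]] <- lookup[[col]][idx]
  unmatched <- sum(is.na(idx))
  if (unmatched) message(unmatched, " record(s) not matched to geography")
  structure(records, n_unmatched = unmatched)
}

#' Characteristics table by wood-burner presence
#'
#' Builds a two-column characteristics table in the style of a baseline
#' table: for each level of each characteristic, the count of properties and
#' the percentage within the wood/no-wood column. Percentages are computed
#' over non-missing values of that characteristic; `Missing` rows are
#' reported separately with no percentage. Accepts either one row per
#' property or pre-aggregated rows with a count column (`weights`).
#'
#' @param properties data.frame of latest-certificate properties.
#' @param flag name of the logical (or "Yes"/"No") column splitting the
#'   columns, default `"wood_fuel"`.
#' @param characteristics character vector of column names to tabulate.
#' @param weights optional name of a count column for pre-aggregated input.
#' @param missing_labels values (besides `NA`) treated as missing.
#' @return data.frame with columns `characteristic`, `level`, `flag`,
#'   `count`, `pct` (NA for missing rows).
#' @export
summarise_by_flag <- function(properties, flag = "wood_fuel",
                              characteristics = intersect(
                                c("property_type", "tenure", "sca", "urban"),
                                names(properties)),
                              weights = NULL,
                              missing_labels = c("", "missing", "Missing")) {
  if (!nrow(properties))
    return(data.frame(characteristic = character(), level = character(),
                      flag = logical(), count = numeric(), pct = numeric()))
  stopifnot(flag %in% names(properties), length(characteristics) > 0)
  w <- if (is.null(weights)) rep(1, nrow(properties))
       else as.numeric(properties[[weights]])
  fl <- properties[[flag]]
  if (!is.logical(fl)) fl <- tolower(as.character(fl)) %in% c("yes", "true", "1")
  out <- list()
  for (ch in characteristics) {
    lev <- as.character(properties[[ch]])
    is_miss <- is.na(lev) | lev %in% missing_labels
    for (f in c(FALSE, TRUE)) {
      sel <- fl == f & !is.na(fl)
      tot <- sum(w[sel & !is_miss])
      levels_here <- sort(unique(lev[sel & !is_miss]))
      for (lv in levels_here) {
        cnt <- sum(w[sel & !is_miss & lev == lv])
        out[[length(out) + 1L]] <- data.frame(
          characteristic = ch, level = lv, flag = f, count = cnt,
          pct = if (tot > 0) 100 * cnt / tot else NA_real_)
      }
      n_miss <- sum(w[sel & is_miss])
      if (n_miss > 0)
        out[[length(out) + 1L]] <- data.frame(
          characteristic = ch, level = "Missing", flag = f,
          count = n_miss, pct = NA_real_)
    }
  }
  do.call(rbind, out)
}
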