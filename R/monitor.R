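#' Estimated burner count within a circular buffer
#'
#' The small-area estimates are areal quantities (one count per LSOA), so
#' counting "burners within r of a monitor" needs an apportionment rule.
#' The default assumes uniform density within each LSOA and apportions each
#' LSOA's count by the fraction of its area intersecting the disc. A point
#' mode is available when per-property coordinates exist (as in synthetic
#' data); the two agree under spatial uniformity.
#'
#' @param polys named list of polygon vertex matrices (projected metres),
#'   keyed by geography code.
#' @param values named numeric vector of estimated counts, keyed to match
#'   `polys`.
#' @param site numeric length-2 site coordinates (same CRS).
#' @param radius buffer radius in metres.
#' @param mode `"area"` (areal apportionment) or `"point"`.
#' @param points for `"point"` mode: data.frame with `x`, `y` and
#'   optionally `weight`.
#' @return estimated count within the buffer (real, >= 0). A site whose
#'   buffer intersects no polygon returns 0 with a warning.
#' @export
buffer_count <- function(polys, values, site, radius,
                         mode = c("area", "point"), points = NULL) {
  mode <- match.arg(mode)
  stopifnot(radius > 0, length(site) == 2)
  if (mode == "point") {
    stopifnot(!is.null(points), all(c("x", "y") %in% names(points)))
    w <- if ("weight" %in% names(points)) points$weight else rep(1, nrow(points))
    d2 <- (points$x - site[1])^2 + (points$y - site[2])^2
    return(sum(w[d2 <= radius^2]))
  }
  ids <- intersect(names(polys), names(values))
  total <- 0
  covered <- FALSE
  for (id in ids) {
    v <- values[[id]]
    if (is.na(v) || v == 0) {
      # still need to know whether the buffer touches the study area
      if (!covered &&
          disc_polygon_area(polys[[id]], site, radius) > 0) covered <- TRUE
      next
    }
    inter <- disc_polygon_area(polys[[id]], site, radius)
    if (inter > 0) {
      covered <- TRUE
      total <- total + v * inter / polygon_area(polys[[id]])
    }
  }
  if (!covered) warning("site buffer outside polygon coverage; count is 0")
  total
}

#' Estimated burner count in a site's 1 km grid square
#'
#' Apportions small-area counts into the aligned grid cell containing the
#' site, by intersection area. Cells are half-open, `[x0, x0 + cell)`, so a
#' site on a cell edge belongs to the cell on its upper side.
#'
#' @inheritParams buffer_count
#' @param cell cell size in metres (default 1000).
#' @param origin grid origin (default `c(0, 0)`, i.e. the national grid of
#'   the projection).
#' @return apportioned count for the cell containing the site.
#' @export
grid_count <- function(polys, values, site, cell = 1000, origin = c(0, 0)) {
  x0 <- floor((site[1] - origin[1]) / cell) * cell + origin[1]
  y0 <- floor((site[2] - origin[2]) / cell) * cell + origin[2]
  ids <- intersect(names(polys), names(values))
  total <- 0
  covered <- FALSE
  for (id in ids) {
    inter <- rect_polygon_area(polys[[id]], x0, x0 + cell, y0, y0 + cell)
    if (inter > 0) {
      covered <- TRUE
      v <- values[[id]]
      if (!is.na(v)) total <- total + v * inter / polygon_area(polys[[id]])
    }
  }
  if (!covered) warning("site grid cell outside polygon coverage; count is 0")
  total
}

#' Apportion counts onto a full grid
#'
#' Distributes every polygon's count over all grid cells it intersects
#' (area-weighted), returning one row per non-empty cell. Cell totals sum
#' to the total input count whenever the grid covers the polygons.
#'
#' @inheritParams grid_count
#' @return data.frame `x0`, `y0`, `count`.
#' @export
grid_count_table <- function(polys, values, cell = 1000, origin = c(0, 0)) {
  ids <- intersect(names(polys), names(values))
  acc <- new.env(parent = emptyenv())
  for (id in ids) {
    v <- values[[id]]
    if (is.na(v) || v == 0) next
    m <- ring_matrix(polys[[id]])
    parea <- polygon_area(polys[[id]])
    cx <- seq(floor((min(m[, 1]) - origin[1]) / cell),
              ceiling((max(m[, 1]) - origin[1]) / cell) - 1L)
    cy <- seq(floor((min(m[, 2]) - origin[2]) / cell),
              ceiling((max(m[, 2]) - origin[2]) / cell) - 1L)
    for (i in cx) for (j in cy) {
      x0 <- i * cell + origin[1]; y0 <- j * cell + origin[2]
      inter <- rect_polygon_area(m, x0, x0 + cell, y0, y0 + cell)
      if (inter > 0) {
        key <- paste(i, j)
        acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) +
          v * inter / parea
      }
    }
  }
  keys <- ls(acc)
  if (!length(keys))
    return(data.frame(x0 = numeric(), y0 = numeric(), count = numeric()))
  ij <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
  out <- data.frame(x0 = as.numeric(ij[, 1]) * cell + origin[1],
                    y0 = as.numeric(ij[, 2]) * cell + origin[2],
                    count = vapply(keys, function(k) acc[[k]], numeric(1)))
  rownames(out) <- NULL
  out[order(out$x0, out$y0), ]
}

season_months <- list(winter = c(12L, 1L, 2L), summer = c(6L, 7L, 8L))

#' Peak minus off-peak PM2.5 difference per site
#'
#' The wood-burning signal statistic: mean PM2.5 during peak burning hours
#' (7pm-1am, i.e. hours 19-23 and 0) minus mean PM2.5 during off-peak hours
#' (5am-5pm, hours 5-16), within a season (winter = DJF, summer = JJA) and
#' day type (weekday Mon-Fri, weekend Sat-Sun). The hour after midnight
#' takes the day-type of its own calendar date. Missing hours are skipped;
#' a site needs at least `min_hours` valid hours on *each* side, otherwise
#' its difference is `NA`.
#'
#' @param measurements data.frame `site_id`, `timestamp` (POSIXct or
#'   ISO-8601 character, fixed-offset local clock time), `pm25`.
#' @param season `"winter"` or `"summer"`.
#' @param daytype `"weekday"`, `"weekend"` or `"all"`.
#' @param peak_hours,offpeak_hours hour-of-day memberships (disjoint).
#' @param min_hours minimum valid hours per side (default 24).
#' @return data.frame `site_id`, `peak_diff`, `mean_pm25` (mean over all
#'   valid season/day-type hours), `n_peak`, `n_offpeak`.
#' @export
peak_offpeak_diff <- function(measurements,
                              season = c("winter", "summer"),
                              daytype = c("weekday", "weekend", "all"),
                              peak_hours = c(19:23, 0L),
                              offpeak_hours = 5:16,
                              min_hours = 24) {
  season <- match.arg(season)
  daytype <- match.arg(daytype)
  if (length(intersect(peak_hours, offpeak_hours)))
    stop("peak and off-peak hour sets must be disjoint")
  dt <- as.data.table(measurements)
  stopifnot(all(c("site_id", "timestamp", "pm25") %in% names(dt)))
  if (!inherits(dt$timestamp, "POSIXct")) {
    fmt <- if (any(grepl("T", utils::head(dt$timestamp, 5), fixed = TRUE)))
      "%Y-%m-%dT%H:%M:%S" else "%Y-%m-%d %H:%M:%S"
    dt[, timestamp := as.POSIXct(as.character(timestamp), tz = "UTC",
                                 format = fmt)]
  }
  dt[, `:=`(month = month(timestamp),
            hour = hour(timestamp),
            wd = wday(timestamp))]  # 1 = Sunday
  dt <- dt[month %in% season_months[[season]]]
  if (daytype == "weekday") dt <- dt[wd %in% 2:6]
  if (daytype == "weekend") dt <- dt[wd %in% c(1L, 7L)]
  dt <- dt[is.finite(pm25)]
  out <- dt[, {
    pk <- pm25[hour %in% peak_hours]
    op <- pm25[hour %in% offpeak_hours]
    .(peak_diff = if (length(pk) >= min_hours && length(op) >= min_hours)
        mean(pk) - mean(op) else NA_real_,
      mean_pm25 = mean(pm25),
      n_peak = length(pk), n_offpeak = length(op))
  }, by = site_id]
  setorder(out, site_id)
  setDF(out)
  out
}

#' Correlate site exposure with a PM2.5 outcome, with BCa interval
#'
#' One stratum of the validation analysis: Spearman correlation between a
#' site-level exposure (e.g. burners within 1 km, or housing density for
#' the negative control) and an outcome (mean PM2.5 or the peak/off-peak
#' difference), with a BCa bootstrap interval resampling sites.
#'
#' @param x,y paired site-level vectors.
#' @param B,alpha,seed,z_max passed to [bca_ci()].
#' @return one-row data.frame `R`, `ci_low`, `ci_high`, `n_sites`, `B`.
#' @export
correlate_sites <- function(x, y, B = 10000, alpha = 0.05, seed = NULL,
                            z_max = 4) {
  ok <- is.finite(x) & is.finite(y)
  d <- data.frame(x = x[ok], y = y[ok])
  r <- spearman_r(d$x, d$y)
  ci <- suppressWarnings(
    bca_ci(d, function(dd) suppressWarnings(spearman_r(dd$x, dd$y)),
           B = B, alpha = alpha, seed = seed, z_max = z_max))
  data.frame(R = r, ci_low = ci[1], ci_high = ci[2],
             n_sites = nrow(d), B = B)
}

#' Full validation correlation table
#'
#' Runs the monitor-validation analysis for every outcome x season x
#' day-type stratum: exposure is the burner count within a buffer (or any
#' site-level exposure such as housing density for the negative control),
#' outcomes are mean PM2.5 and the peak/off-peak difference.
#'
#' @param exposure data.frame `site_id`, `x` (site exposure).
#' @param measurements hourly PM2.5 table (see [peak_offpeak_diff()]).
#' @param daytypes day types to evaluate (default weekday/weekend).
#' @param B,alpha,seed bootstrap controls.
#' @param min_hours per-side validity threshold.
#' @return data.frame with one row per outcome/season/daytype stratum:
#'   `outcome`, `season`, `daytype`, `R`, `ci_low`, `ci_high`, `n_sites`,
#'   `B`.
#' @export
validation_correlations <- function(exposure, measurements,
                                    daytypes = c("weekday", "weekend"),
                                    B = 10000, alpha = 0.05, seed = NULL,
                                    min_hours = 24) {
  stopifnot(all(c("site_id", "x") %in% names(exposure)))
  rows <- list()
  for (season in c("winter", "summer")) for (dtp in daytypes) {
    po <- peak_offpeak_diff(measurements, season = season, daytype = dtp,
                            min_hours = min_hours)
    m <- merge(exposure, po, by = "site_id")
    for (outc in c("mean_pm25", "peak_diff")) {
      res <- correlate_sites(m$x, m[[outc]], B = B, alpha = alpha,
                             seed = seed)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(outcome = outc, season = season, daytype = dtp), res)
    }
  }
  do.call(rbind, rows)
}
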