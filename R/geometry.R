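## Planar geometry for buffer and grid apportionment.
##
## Polygons are plain two-column matrices (x, y) in a projected CRS in
## metres; rings may be open or closed. All routines are exact (to floating
## point), not rasterised: the disc-polygon intersection uses Green's
## theorem with circular clipping of each edge, which the tests cross-check
## against Monte-Carlo point-in-polygon oracles.

ring_matrix <- function(poly) {
  m <- as.matrix(poly)
  stopifnot(ncol(m) == 2, nrow(m) >= 3)
  # drop a closing vertex identical to the first
  if (nrow(m) > 3 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  m
}

#' Area of a simple polygon
#'
#' Shoelace formula; orientation-independent (absolute value).
#'
#' @param poly two-column matrix of vertex coordinates.
#' @return area in squared coordinate units.
#' @export
polygon_area <- function(poly) {
  m <- ring_matrix(poly)
  x <- m[, 1]; y <- m[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

signed_ring_area <- function(m) {
  x <- m[, 1]; y <- m[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Exact area of the intersection of a disc and a polygon
#'
#' Clips every polygon edge against the circle: sub-segments inside the
#' disc contribute a triangle term with the centre, sub-segments outside
#' contribute the circular-sector term between their endpoint bearings
#' (Green's theorem). Exact for simple polygons of any convexity.
#'
#' @param poly two-column vertex matrix.
#' @param centre numeric length-2 disc centre.
#' @param radius disc radius (> 0).
#' @return intersection area (>= 0).
#' @export
disc_polygon_area <- function(poly, centre, radius) {
  stopifnot(radius > 0, length(centre) == 2)
  m <- ring_matrix(poly)
  if (signed_ring_area(m) < 0) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  m <- sweep(m, 2, as.numeric(centre))
  r2 <- radius^2
  total <- 0
  n <- nrow(m)
  for (i in seq_len(n)) {
    a <- m[i, ]
    b <- m[if (i == n) 1L else i + 1L, ]
    d <- b - a
    dd <- sum(d * d)
    if (dd == 0) next
    # |a + t d|^2 = r^2
    qb <- sum(a * d) / dd
    qc <- (sum(a * a) - r2) / dd
    disc <- qb * qb - qc
    ts <- c(0, 1)
    if (disc > 0) {
      rt <- sqrt(disc)
      ts <- c(ts, -qb - rt, -qb + rt)
    }
    ts <- sort(unique(pmin(pmax(ts, 0), 1)))
    for (j in seq_len(length(ts) - 1)) {
      t0 <- ts[j]; t1 <- ts[j + 1]
      if (t1 <= t0) next
      p0 <- a + t0 * d
      p1 <- a + t1 * d
      pm <- a + 0.5 * (t0 + t1) * d
      if (sum(pm * pm) <= r2) {
        total <- total + (p0[1] * p1[2] - p1[1] * p0[2]) / 2
      } else {
        dth <- atan2(p0[1] * p1[2] - p1[1] * p0[2], sum(p0 * p1))
        total <- total + 0.5 * r2 * dth
      }
    }
  }
  max(total, 0)
}

#' Clip a polygon to an axis-aligned rectangle
#'
#' Sutherland-Hodgman clipping against the four half-planes of
#' `[x0, x1] x [y0, y1]`.
#'
#' @param poly two-column vertex matrix.
#' @param x0,x1,y0,y1 rectangle bounds.
#' @return the clipped vertex matrix (possibly 0 rows).
#' @export
clip_polygon_rect <- function(poly, x0, x1, y0, y1) {
  m <- ring_matrix(poly)
  clip_half <- function(m, inside, intersect) {
    if (!nrow(m)) return(m)
    out <- matrix(numeric(0), ncol = 2)
    n <- nrow(m)
    for (i in seq_len(n)) {
      cur <- m[i, ]
      prv <- m[if (i == 1) n else i - 1L, ]
      cin <- inside(cur); pin <- inside(prv)
      if (cin) {
        if (!pin) out <- rbind(out, intersect(prv, cur))
        out <- rbind(out, cur)
      } else if (pin) {
        out <- rbind(out, intersect(prv, cur))
      }
    }
    out
  }
  ix <- function(p, q, val, axis) {
    t <- (val - p[axis]) / (q[axis] - p[axis])
    p + t * (q - p)
  }
  m <- clip_half(m, function(p) p[1] >= x0, function(p, q) ix(p, q, x0, 1))
  m <- clip_half(m, function(p) p[1] <= x1, function(p, q) ix(p, q, x1, 1))
  m <- clip_half(m, function(p) p[2] >= y0, function(p, q) ix(p, q, y0, 2))
  m <- clip_half(m, function(p) p[2] <= y1, function(p, q) ix(p, q, y1, 2))
  m
}

#' Area of a polygon clipped to a rectangle
#' @inheritParams clip_polygon_rect
#' @return intersection area.
#' @export
rect_polygon_area <- function(poly, x0, x1, y0, y1) {
  m <- clip_polygon_rect(poly, x0, x1, y0, y1)
  if (nrow(m) < 3) return(0)
  polygon_area(m)
}

#' Point-in-polygon test (even-odd rule)
#'
#' @param x,y point coordinates (vectorised).
#' @param poly two-column vertex matrix.
#' @return logical vector.
#' @export
point_in_polygon <- function(x, y, poly) {
  m <- ring_matrix(poly)
  px <- m[, 1]; py <- m[, 2]
  n <- nrow(m)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    cross <- (py[i] > y) != (py[j] > y)
    xi <- px[i] + (y - py[i]) / (py[j] - py[i]) * (px[j] - px[i])
    hit <- cross & (x < xi)
    inside <- xor(inside, hit & !is.na(hit))
    j <- i
  }
  inside
}

#' Read polygons from a GeoJSON FeatureCollection
#'
#' Reads Polygon features (outer ring only) into a named list of vertex
#' matrices, keyed by a feature property.
#'
#' @param path GeoJSON file path.
#' @param id_property feature property holding the geography code
#'   (default `"lsoa"`).
#' @return named list of two-column matrices, with an `area_km2` attribute
#'   vector when coordinates are in metres.
#' @export
read_geojson_polygons <- function(path, id_property = "lsoa") {
  gj <- jsonlite::read_json(path)
  stopifnot(identical(gj$type, "FeatureCollection"))
  polys <- list()
  for (f in gj$features) {
    id <- as.character(f$properties[[id_property]])
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    polys[[id]] <- ring_matrix(m)
  }
  polys
}

#' Write polygons to GeoJSON
#'
#' @param polys named list of two-column vertex matrices.
#' @param path output file.
#' @param id_property property name for the code (default `"lsoa"`).
#' @param properties optional data.frame of extra feature properties, keyed
#'   by a column matching `id_property`.
#' @export
write_geojson_polygons <- function(polys, path, id_property = "lsoa",
                                   properties = NULL) {
  features <- lapply(names(polys), function(id) {
    m <- ring_matrix(polys[[id]])
    m <- rbind(m, m[1, ])  # closed ring
    props <- stats::setNames(list(id), id_property)
    if (!is.null(properties)) {
      row <- properties[properties[[id_property]] == id, , drop = FALSE]
      if (nrow(row) == 1)
        for (col in setdiff(names(row), id_property))
          props[[col]] <- row[[col]][1]
    }
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(m)),
                                                   function(i) as.list(unname(m[i, ]))))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
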