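# Spherical geodesy on WGS84 coordinates (decimal degrees), distances in km.
# At the ~200 km scale of the range checks the spherical approximation and a
# local azimuthal-equidistant plane distort distances far less than the
# 0.5 km boundary tolerance the tests allow.

EARTH_RADIUS_KM <- 6371.0088

deg2rad <- function(x) x * pi / 180

# Project points onto a local azimuthal-equidistant plane centred on
# (lat0, lon0): each point is mapped to (distance * sin(bearing),
# distance * cos(bearing)) from the centre, in km.
aeq_project <- function(lat, lon, lat0, lon0) {
  phi1 <- deg2rad(lat0); lam1 <- deg2rad(lon0)
  phi2 <- deg2rad(lat);  lam2 <- deg2rad(lon)
  dlam <- lam2 - lam1
  cosc <- pmin(1, pmax(-1, sin(phi1) * sin(phi2) + cos(phi1) * cos(phi2) * cos(dlam)))
  c_ <- acos(cosc)
  k <- ifelse(c_ < 1e-12, 1, c_ / sin(c_))
  cbind(x = EARTH_RADIUS_KM * k * cos(phi2) * sin(dlam),
        y = EARTH_RADIUS_KM * k * (cos(phi1) * sin(phi2) -
                                     sin(phi1) * cos(phi2) * cos(dlam)))
}

# Destination point given start, initial bearing (degrees) and distance (km).
destination_point <- function(lat, lon, bearing_deg, dist_km) {
  phi1 <- deg2rad(lat); lam1 <- deg2rad(lon)
  th <- deg2rad(bearing_deg); d <- dist_km / EARTH_RADIUS_KM
  phi2 <- asin(sin(phi1) * cos(d) + cos(phi1) * sin(d) * cos(th))
  lam2 <- lam1 + atan2(sin(th) * sin(d) * cos(phi1),
                       cos(d) - sin(phi1) * sin(phi2))
  cbind(lat = phi2 * 180 / pi,
        lon = ((lam2 * 180 / pi + 540) %% 360) - 180)
}

# Squared distance from points P (n x 2) to segment AB in the plane.
dist_point_segment <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  L2 <- vx * vx + vy * vy
  if (L2 < 1e-18) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
  sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
}

# TRUE for points inside a convex polygon (vertices in hull order).
inside_convex <- function(px, py, hx, hy) {
  n <- length(hx)
  if (n < 3L) return(rep(FALSE, length(px)))
  inside <- rep(TRUE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cross <- (hx[j] - hx[i]) * (py - hy[i]) - (hy[j] - hy[i]) * (px - hx[i])
    inside <- inside & cross >= -1e-9
  }
  inside
}

#' Build a buffered search region around detection traps
#'
#' The region is the convex hull of the trap coordinates extended outwards by
#' `radius_km`: with one trap this is a geodesic disc, with two (or collinear)
#' traps a stadium around the segment, otherwise a buffered polygon. All
#' geometry is computed on a local azimuthal-equidistant plane centred on the
#' traps' centroid.
#'
#' @param lat,lon trap coordinates, WGS84 decimal degrees.
#' @param radius_km buffer distance in kilometres (default 200).
#' @return an object of class `search_region`.
#' @export
build_search_region <- function(lat, lon, radius_km = 200) {
  if (length(lat) == 0L) stop("zero traps: species cannot have been detected")
  stopifnot(length(lat) == length(lon), radius_km > 0,
            all(abs(lat) <= 90), all(abs(lon) <= 180))
  lat0 <- mean(lat); lon0 <- mean(lon)
  xy <- aeq_project(lat, lon, lat0, lon0)
  h <- if (nrow(xy) >= 3L) grDevices::chull(xy[, 1], xy[, 2]) else seq_len(nrow(xy))
  hull <- xy[h, , drop = FALSE]
  # chull returns clockwise order; reverse to counter-clockwise for the
  # cross-product containment test
  if (nrow(hull) >= 3L) hull <- hull[rev(seq_len(nrow(hull))), , drop = FALSE]
  structure(list(lat0 = lat0, lon0 = lon0, hull = hull, radius_km = radius_km),
            class = "search_region")
}

#' Test whether points fall inside a search region
#'
#' A point is inside when its distance to the trap convex hull (zero for
#' points within the hull itself) does not exceed the buffer radius.
#'
#' @param region a [build_search_region()] result.
#' @param lat,lon query coordinates (vectors).
#' @return logical vector.
#' @export
region_contains <- function(region, lat, lon) {
  stopifnot(inherits(region, "search_region"))
  if (length(lat) == 0L) return(logical())
  p <- aeq_project(lat, lon, region$lat0, region$lon0)
  hx <- region$hull[, 1]; hy <- region$hull[, 2]
  n <- nrow(region$hull)
  d <- if (n == 1L) {
    sqrt((p[, 1] - hx)^2 + (p[, 2] - hy)^2)
  } else {
    dmin <- rep(Inf, nrow(p))
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      if (n == 2L && i == 2L) break  # segment, not a loop
      dmin <- pmin(dmin, dist_point_segment(p[, 1], p[, 2],
                                            hx[i], hy[i], hx[j], hy[j]))
    }
    dmin[inside_convex(p[, 1], p[, 2], hx, hy)] <- 0
    dmin
  }
  d <= region$radius_km
}

#' @export
print.search_region <- function(x, ...) {
  cat(sprintf("search_region: %d hull vertices, %g km buffer, centred (%.4f, %.4f)\n",
              nrow(x$hull), x$radius_km, x$lat0, x$lon0))
  invisible(x)
}
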