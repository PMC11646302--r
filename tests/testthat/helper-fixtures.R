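# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's own code paths: geodesy uses haversine + great-circle
# interpolation, translation uses Biostrings, grouping/summing is brute
# force.

R_EARTH <- 6371.0088

hav_dist <- function(lat1, lon1, lat2, lon2) {
  p <- pi / 180
  a <- sin((lat2 - lat1) * p / 2)^2 +
    cos(lat1 * p) * cos(lat2 * p) * sin((lon2 - lon1) * p / 2)^2
  2 * R_EARTH * asin(pmin(1, sqrt(a)))
}

# great-circle interpolation between two points (slerp on the unit sphere)
gc_interp <- function(lat1, lon1, lat2, lon2, n) {
  p <- pi / 180
  v1 <- c(cos(lat1 * p) * cos(lon1 * p), cos(lat1 * p) * sin(lon1 * p), sin(lat1 * p))
  v2 <- c(cos(lat2 * p) * cos(lon2 * p), cos(lat2 * p) * sin(lon2 * p), sin(lat2 * p))
  w <- acos(min(1, max(-1, sum(v1 * v2))))
  t <- seq(0, 1, length.out = n)
  if (w < 1e-12) {
    m <- matrix(v1, nrow = n, ncol = 3, byrow = TRUE)
  } else {
    m <- outer(sin((1 - t) * w) / sin(w), v1) + outer(sin(t * w) / sin(w), v2)
  }
  cbind(lat = asin(pmax(-1, pmin(1, m[, 3]))) / p, lon = atan2(m[, 2], m[, 1]) / p)
}

# brute-force oracle: distance (km) from a query point to the convex hull of
# the trap points, hull edges traced as dense great-circle samples; 0 when
# the query is inside the hull (equirectangular planar containment).
oracle_hull_distance <- function(qlat, qlon, tlat, tlon, step_km = 0.05) {
  n <- length(tlat)
  if (n >= 3) {
    lat0 <- mean(tlat); lon0 <- mean(tlon)
    ex <- function(la, lo) cbind((lo - lon0) * 111.32 * cos(lat0 * pi / 180),
                                 (la - lat0) * 110.574)
    xy <- ex(tlat, tlon)
    h <- grDevices::chull(xy[, 1], xy[, 2])
    hull_xy <- xy[h, , drop = FALSE]
    q <- ex(qlat, qlon)
    inside <- TRUE
    m <- nrow(hull_xy)
    sgn <- 0
    for (i in seq_len(m)) {
      j <- if (i == m) 1L else i + 1L
      cr <- (hull_xy[j, 1] - hull_xy[i, 1]) * (q[2] - hull_xy[i, 2]) -
        (hull_xy[j, 2] - hull_xy[i, 2]) * (q[1] - hull_xy[i, 1])
      if (abs(cr) > 1e-12) {
        if (sgn == 0) sgn <- sign(cr)
        else if (sign(cr) != sgn) { inside <- FALSE; break }
      }
    }
    if (inside) return(0)
    vlat <- tlat[h]; vlon <- tlon[h]
  } else {
    vlat <- tlat; vlon <- tlon
  }
  best <- Inf
  m <- length(vlat)
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    if (m == 1L) {
      best <- min(best, hav_dist(qlat, qlon, vlat, vlon))
      break
    }
    L <- hav_dist(vlat[i], vlon[i], vlat[j], vlon[j])
    pts <- gc_interp(vlat[i], vlon[i], vlat[j], vlon[j],
                     max(2L, ceiling(L / step_km)))
    best <- min(best, hav_dist(qlat, qlon, pts[, "lat"], pts[, "lon"]))
  }
  best
}

# Biostrings-backed translation oracle, vectorised over sequences: TRUE if
# any forward frame is stop-free under NCBI translation table 5
bios_any_frame_stop_free <- function(seqs) {
  gc5 <- Biostrings::getGeneticCode("5")
  per_frame <- vapply(0:2, function(o) {
    n <- nchar(seqs) - o
    n <- n - n %% 3
    aa <- Biostrings::translate(
      Biostrings::DNAStringSet(substr(seqs, o + 1, o + n)),
      genetic.code = gc5, if.fuzzy.codon = "solve")
    !grepl("*", as.character(aa), fixed = TRUE)
  }, logical(length(seqs)))
  apply(matrix(per_frame, ncol = 3), 1, any)
}

random_acgt <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                 collapse = "")

# hand-sized OTU table: 3 OTUs, two samples x two replicates, two negatives
tiny_table <- function() {
  counts <- rbind(
    OTU1 = c(a1 = 3L, b1 = 4L, a2 = 0L, b2 = 7L, n1 = 2L, n2 = 4L),
    OTU2 = c(a1 = 10L, b1 = 10L, a2 = 5L, b2 = 6L, n1 = 0L, n2 = 0L),
    OTU3 = c(a1 = 0L, b1 = 0L, a2 = 0L, b2 = 0L, n1 = 3L, n2 = 1L))
  otu_table(counts,
            replicate_pairs = data.frame(sample_id = c("s1", "s2"),
                                         lib_a = c("a1", "a2"),
                                         lib_b = c("b1", "b2")),
            negative_ids = c("n1", "n2"))
}

small_spec <- function(seed = 7, ...) {
  community_spec(n_orders = 4, species_per_order = 30, n_traps = 6,
                 samples_per_trap = 6, seed = seed, ...)
}
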