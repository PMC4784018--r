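#' Metric configuration
#'
#' Measurement settings shared by all area/distance computations.
#'
#' In `"planar"` mode coordinates are kilometres on an abstract plane and
#' measures are exact (shoelace areas, Euclidean distances). In `"spherical"`
#' mode coordinates are lon/lat degrees on a reference ellipsoid: ring edges
#' are measured as geodesic arcs for polygon areas, while for
#' boundary-to-boundary distances candidate boundary points are interpolated
#' linearly in lon/lat along each edge and joined by geodesics (for the
#' sub-degree edges these layers carry the two edge readings differ far
#' below every tolerance in play).
#'
#' @param mode `"planar"` or `"spherical"`.
#' @param ellipsoid `"WGS84"`, `"sphere"` (authalic Earth sphere,
#'   R = 6371007.181 m), or a list with elements `a` (semi-major axis, m)
#'   and `f` (flattening).
#' @param distance_tolerance_km distances at or below this are reported as 0
#'   (touching). Must be > 0.
#' @return A list of class `metric_config`.
#' @export
metric_config <- function(mode = c("planar", "spherical"),
                          ellipsoid = "WGS84",
                          distance_tolerance_km = 1e-6) {
  mode <- match.arg(mode)
  if (!is.numeric(distance_tolerance_km) || distance_tolerance_km <= 0)
    stop("distance_tolerance_km must be > 0")
  if (is.character(ellipsoid)) {
    ellipsoid <- switch(ellipsoid,
      WGS84 = list(a = 6378137, f = 1 / 298.257223563),
      sphere = list(a = 6371007.181, f = 0),
      stop("unknown ellipsoid: ", ellipsoid))
  }
  stopifnot(is.list(ellipsoid), is.numeric(ellipsoid$a), is.numeric(ellipsoid$f))
  structure(list(mode = mode, ellipsoid = ellipsoid,
                 distance_tolerance_km = distance_tolerance_km),
            class = "metric_config")
}

check_lonlat <- function(g) {
  v <- do.call(rbind, unlist(unclass(g), recursive = FALSE))
  if (any(abs(v[, 2L]) > 90)) stop("latitude outside [-90, 90]")
  if (any(abs(v[, 1L]) > 360)) stop("longitude outside [-360, 360]")
  e <- geom_edges(g)
  if (nrow(e) && any(abs(e[, "x2"] - e[, "x1"]) > 180))
    stop("edge spans more than 180 degrees of longitude; ",
         "split the polygon at the antimeridian before measuring")
  invisible(TRUE)
}

#' Polygon area in square kilometres
#'
#' Planar mode: shoelace area (exterior minus holes, summed over member
#' polygons, which are assumed interior-disjoint — true for every overlay
#' product of this package). Spherical mode: geodesic polygon area on the
#' configured ellipsoid, ring edges read as geodesic arcs. Ring orientation
#' is normalised, never an error; degenerate rings measure 0.
#'
#' @param g an `est_geom`.
#' @param config a [metric_config()].
#' @return Area in km^2 (>= 0).
#' @export
polygon_area_km2 <- function(g, config = metric_config()) {
  stopifnot(inherits(g, "est_geom"), inherits(config, "metric_config"))
  if (geom_is_empty(g)) return(0)
  if (config$mode == "planar") return(geom_area_planar(g))
  check_lonlat(g)
  a <- config$ellipsoid$a; f <- config$ellipsoid$f
  total <- 0
  for (p in g) {
    ring_area <- function(r) {
      abs(geosphere::areaPolygon(r, a = a, f = f)) / 1e6
    }
    pa <- ring_area(p[[1L]])
    if (length(p) > 1L) pa <- pa - sum(vapply(p[-1L], ring_area, 0))
    total <- total + max(pa, 0)
  }
  total
}

# ---- planar distance primitives -------------------------------------------

# Min distance between two edge sets (matrices from geom_edges), Euclidean.
# Returns 0 when any segments properly cross; touching is caught by the
# point-to-segment terms.
segs_min_dist_planar <- function(E1, E2) {
  if (nrow(E1) == 0L || nrow(E2) == 0L) return(Inf)
  i <- rep(seq_len(nrow(E1)), times = nrow(E2))
  j <- rep(seq_len(nrow(E2)), each = nrow(E1))
  ax <- E1[i, "x1"]; ay <- E1[i, "y1"]; bx <- E1[i, "x2"]; by <- E1[i, "y2"]
  cx <- E2[j, "x1"]; cy <- E2[j, "y1"]; dx <- E2[j, "x2"]; dy <- E2[j, "y2"]
  pt_seg <- function(px, py, sx, sy, tx, ty) {
    vx <- tx - sx; vy <- ty - sy
    L2 <- vx * vx + vy * vy
    t <- ifelse(L2 > 0, pmin(1, pmax(0, ((px - sx) * vx + (py - sy) * vy) / L2)), 0)
    qx <- sx + t * vx; qy <- sy + t * vy
    sqrt((px - qx)^2 + (py - qy)^2)
  }
  d <- pmin(
    pt_seg(ax, ay, cx, cy, dx, dy), pt_seg(bx, by, cx, cy, dx, dy),
    pt_seg(cx, cy, ax, ay, bx, by), pt_seg(dx, dy, ax, ay, bx, by))
  crs <- function(ox, oy, px, py, qx, qy) (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  d1 <- crs(ax, ay, bx, by, cx, cy); d2 <- crs(ax, ay, bx, by, dx, dy)
  d3 <- crs(cx, cy, dx, dy, ax, ay); d4 <- crs(cx, cy, dx, dy, bx, by)
  d[d1 * d2 < 0 & d3 * d4 < 0] <- 0
  min(d)
}

# One vertex of g, for containment probes.
geom_any_vertex <- function(g) g[[1L]][[1L]][1L, ]

# Planar distance between two geometries: 0 when boundaries cross/touch or
# one geometry lies inside the other; else min boundary-to-boundary distance.
geom_dist_planar <- function(g1, g2) {
  e1 <- geom_edges(g1); e2 <- geom_edges(g2)
  d <- segs_min_dist_planar(e1, e2)
  if (d > 0) {
    v1 <- geom_any_vertex(g1); v2 <- geom_any_vertex(g2)
    if (pt_in_geom(e2, v1[1L], v1[2L]) || pt_in_geom(e1, v2[1L], v2[2L])) d <- 0
  }
  d
}

# ---- spherical distance ----------------------------------------------------

# Geodesic distance (km) between two lon/lat points sets, vectorized.
geo_dist_km <- function(p, q, ell) {
  geosphere::distGeo(p, q, a = ell$a, f = ell$f) / 1000
}

# Iteratively refined geodesic min distance between two lon/lat segments,
# each interpolated linearly in lon/lat.
seg_pair_min_geo <- function(a1, a2, b1, b2, ell, iters = 40L, npts = 7L) {
  s0 <- 0; s1 <- 1; t0 <- 0; t1 <- 1
  best <- Inf
  for (it in seq_len(iters)) {
    ss <- seq(s0, s1, length.out = npts)
    tt <- seq(t0, t1, length.out = npts)
    P <- cbind(a1[1L] + ss * (a2[1L] - a1[1L]), a1[2L] + ss * (a2[2L] - a1[2L]))
    Q <- cbind(b1[1L] + tt * (b2[1L] - b1[1L]), b1[2L] + tt * (b2[2L] - b1[2L]))
    i <- rep(seq_len(npts), times = npts)
    j <- rep(seq_len(npts), each = npts)
    d <- geo_dist_km(P[i, , drop = FALSE], Q[j, , drop = FALSE], ell)
    k <- which.min(d)
    best <- d[k]
    ik <- i[k]; jk <- j[k]
    ns0 <- ss[max(1L, ik - 1L)]; ns1 <- ss[min(npts, ik + 1L)]
    nt0 <- tt[max(1L, jk - 1L)]; nt1 <- tt[min(npts, jk + 1L)]
    if ((ns1 - ns0) < 1e-14 && (nt1 - nt0) < 1e-14) break
    s0 <- ns0; s1 <- ns1; t0 <- nt0; t1 <- nt1
  }
  best
}

geom_dist_spherical <- function(g1, g2, ell) {
  check_lonlat(g1); check_lonlat(g2)
  # topology (crossing / containment) in lon/lat coordinates
  e1 <- geom_edges(g1); e2 <- geom_edges(g2)
  if (segs_min_dist_planar(e1, e2) == 0) return(0)
  v1 <- geom_any_vertex(g1); v2 <- geom_any_vertex(g2)
  if (pt_in_geom(e2, v1[1L], v1[2L]) || pt_in_geom(e1, v2[1L], v2[2L])) return(0)
  # prune segment pairs by endpoint geodesic distances, then refine
  n1 <- nrow(e1); n2 <- nrow(e2)
  i <- rep(seq_len(n1), times = n2)
  j <- rep(seq_len(n2), each = n1)
  dep <- pmin(
    geo_dist_km(e1[i, c("x1", "y1"), drop = FALSE], e2[j, c("x1", "y1"), drop = FALSE], ell),
    geo_dist_km(e1[i, c("x1", "y1"), drop = FALSE], e2[j, c("x2", "y2"), drop = FALSE], ell),
    geo_dist_km(e1[i, c("x2", "y2"), drop = FALSE], e2[j, c("x1", "y1"), drop = FALSE], ell),
    geo_dist_km(e1[i, c("x2", "y2"), drop = FALSE], e2[j, c("x2", "y2"), drop = FALSE], ell))
  len1 <- geo_dist_km(e1[, c("x1", "y1"), drop = FALSE], e1[, c("x2", "y2"), drop = FALSE], ell)
  len2 <- geo_dist_km(e2[, c("x1", "y1"), drop = FALSE], e2[, c("x2", "y2"), drop = FALSE], ell)
  # endpoint min overestimates the true pair distance by at most half the
  # longer edge length; prune with that margin
  slack <- pmax(len1[i], len2[j])
  cand <- which(dep <= min(dep) + slack)
  best <- Inf
  for (k in cand) {
    ek <- e1[i[k], ]; fk <- e2[j[k], ]
    d <- seg_pair_min_geo(c(ek[["x1"]], ek[["y1"]]), c(ek[["x2"]], ek[["y2"]]),
                          c(fk[["x1"]], fk[["y1"]]), c(fk[["x2"]], fk[["y2"]]), ell)
    if (d < best) best <- d
  }
  best
}

as_patch_geoms <- function(x) {
  if (inherits(x, "est_geom")) return(list(x))
  if (is.data.frame(x)) x <- x$geometry
  stopifnot(is.list(x), all(vapply(x, inherits, TRUE, "est_geom")))
  x
}

#' Minimum source-receptor distance between patch sets
#'
#' The minimum, over all source-receptor patch pairs, of the shortest
#' boundary-to-boundary distance. Adjacent (touching or overlapping) pairs
#' give exactly 0. Distances are Euclidean km in planar mode and geodesics on
#' the configured ellipsoid in spherical mode (polygon edges interpreted as
#' straight lines in lon/lat).
#'
#' @param sources,receptors non-empty lists of `est_geom` patches (or patch
#'   tables with a `geometry` list-column, as returned by
#'   [clip_to_countries()]).
#' @param config a [metric_config()].
#' @return Distance in km (>= 0; values at or below the configured tolerance
#'   collapse to 0).
#' @export
min_patch_distance_km <- function(sources, receptors, config = metric_config()) {
  stopifnot(inherits(config, "metric_config"))
  src <- as_patch_geoms(sources)
  rec <- as_patch_geoms(receptors)
  if (length(src) == 0L || length(rec) == 0L)
    stop("min_patch_distance_km() needs at least one patch of each role")
  best <- Inf
  for (s in src) for (r in rec) {
    d <- if (config$mode == "planar") geom_dist_planar(s, r)
         else geom_dist_spherical(s, r, config$ellipsoid)
    if (d < best) best <- d
    if (best == 0) return(0)
  }
  if (best <= config$distance_tolerance_km) 0 else best
}

#' Brute-force minimum-distance oracle
#'
#' Independent check for [min_patch_distance_km()]: samples points uniformly
#' (endpoints included) along every boundary edge of every patch and takes
#' the minimum pairwise point distance; crossing or contained pairs give 0.
#' The result upper-bounds the true boundary distance and converges to it as
#' `samples_per_edge` grows.
#'
#' @inheritParams min_patch_distance_km
#' @param samples_per_edge number of sample points per edge (>= 2).
#' @return Distance in km.
#' @export
brute_force_min_distance <- function(sources, receptors, samples_per_edge,
                                     config = metric_config()) {
  stopifnot(samples_per_edge >= 2)
  src <- as_patch_geoms(sources)
  rec <- as_patch_geoms(receptors)
  if (length(src) == 0L || length(rec) == 0L)
    stop("brute_force_min_distance() needs at least one patch of each role")
  sample_edges <- function(E) {
    tt <- seq(0, 1, length.out = samples_per_edge)
    n <- nrow(E)
    i <- rep(seq_len(n), each = length(tt))
    t2 <- rep(tt, times = n)
    cbind(E[i, "x1"] + t2 * (E[i, "x2"] - E[i, "x1"]),
          E[i, "y1"] + t2 * (E[i, "y2"] - E[i, "y1"]))
  }
  e1 <- do.call(rbind, lapply(src, geom_edges))
  e2 <- do.call(rbind, lapply(rec, geom_edges))
  if (segs_min_dist_planar(e1, e2) == 0) return(0)
  v1 <- e1[1L, c("x1", "y1")]; v2 <- e2[1L, c("x1", "y1")]
  if (pt_in_geom(e2, v1[1L], v1[2L]) || pt_in_geom(e1, v2[1L], v2[2L])) return(0)
  P <- sample_edges(e1)
  Q <- sample_edges(e2)
  if (config$mode == "planar") {
    d2 <- outer(P[, 1L], Q[, 1L], "-")^2 + outer(P[, 2L], Q[, 2L], "-")^2
    sqrt(min(d2))
  } else {
    best <- Inf
    chunk <- max(1L, floor(2e6 / nrow(Q)))
    for (start in seq(1L, nrow(P), by = chunk)) {
      idx <- start:min(nrow(P), start + chunk - 1L)
      i <- rep(idx, times = nrow(Q))
      j <- rep(seq_len(nrow(Q)), each = length(idx))
      best <- min(best, min(geo_dist_km(P[i, , drop = FALSE],
                                        Q[j, , drop = FALSE], config$ellipsoid)))
    }
    best
  }
}
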