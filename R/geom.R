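#' Geometry containers
#'
#' Vector geometries are held in a minimal multipolygon container,
#' `est_geom`: a list of polygons, where each polygon is a list of rings and
#' each ring is an open (first vertex not repeated) two-column numeric matrix
#' of vertex coordinates. The first ring of a polygon is the exterior
#' boundary; any further rings are holes. Coordinates are kilometres in
#' planar mode and lon/lat degrees (WGS84-style axis order) in spherical
#' mode; the container itself is unit-agnostic.
#'
#' @param polygons list of polygons (each a list of rings).
#' @return An object of class `est_geom`.
#' @export
est_geom <- function(polygons = list()) {
  stopifnot(is.list(polygons))
  polygons <- lapply(polygons, function(p) {
    if (is.matrix(p)) p <- list(p)
    lapply(p, as_ring)
  })
  structure(polygons, class = "est_geom")
}

as_ring <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (ncol(m) != 2L) stop("ring must be a two-column matrix")
  # drop an explicitly closed last vertex
  n <- nrow(m)
  if (n > 1L && all(m[1L, ] == m[n, ])) m <- m[-n, , drop = FALSE]
  if (nrow(m) < 3L) stop("ring must have at least 3 distinct vertices")
  dimnames(m) <- NULL
  m
}

#' @export
print.est_geom <- function(x, ...) {
  np <- length(x)
  nv <- sum(vapply(x, function(p) sum(vapply(p, nrow, 0L)), 0L))
  cat(sprintf("<est_geom: %d polygon%s, %d vertices>\n",
              np, if (np == 1L) "" else "s", nv))
  invisible(x)
}

#' Axis-aligned rectangle geometry
#'
#' @param xmin,ymin,xmax,ymax rectangle bounds (km in planar mode,
#'   degrees in spherical mode).
#' @return An `est_geom` with one rectangular polygon.
#' @export
geom_rect <- function(xmin, ymin, xmax, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  est_geom(list(list(rbind(
    c(xmin, ymin), c(xmax, ymin), c(xmax, ymax), c(xmin, ymax)
  ))))
}

#' Is a geometry empty?
#' @param g an `est_geom`.
#' @return Logical scalar.
#' @export
geom_is_empty <- function(g) length(g) == 0L

#' Combine geometries into one multipolygon
#'
#' Concatenates the member polygons of several geometries. No dissolve is
#' performed; use [geom_union()] when inputs may overlap.
#' @param ... `est_geom` objects or a single list of them.
#' @return An `est_geom`.
#' @export
geom_combine <- function(...) {
  gs <- list(...)
  if (length(gs) == 1L && !inherits(gs[[1L]], "est_geom")) gs <- gs[[1L]]
  est_geom(do.call(c, c(lapply(gs, unclass), list(list()))))
}

#' Bounding box of a geometry
#' @param g an `est_geom`.
#' @return Named numeric vector `c(xmin, ymin, xmax, ymax)`.
#' @export
geom_bbox <- function(g) {
  if (geom_is_empty(g)) return(c(xmin = NA_real_, ymin = NA_real_,
                                 xmax = NA_real_, ymax = NA_real_))
  v <- do.call(rbind, unlist(g, recursive = FALSE))
  c(xmin = min(v[, 1L]), ymin = min(v[, 2L]),
    xmax = max(v[, 1L]), ymax = max(v[, 2L]))
}

# Edge table: one row per directed ring edge, with the polygon index it
# belongs to. Columns x1, y1, x2, y2, poly.
geom_edges <- function(g) {
  out <- vector("list", 64L)
  k <- 0L
  for (ip in seq_along(g)) {
    for (ring in g[[ip]]) {
      n <- nrow(ring)
      nxt <- c(2:n, 1L)
      k <- k + 1L
      if (k > length(out)) out <- c(out, vector("list", length(out)))
      out[[k]] <- cbind(x1 = ring[, 1L], y1 = ring[, 2L],
                        x2 = ring[nxt, 1L], y2 = ring[nxt, 2L],
                        poly = ip)
    }
  }
  if (k == 0L) {
    return(matrix(numeric(0), ncol = 5L,
                  dimnames = list(NULL, c("x1", "y1", "x2", "y2", "poly"))))
  }
  do.call(rbind, out[seq_len(k)])
}

# Point-in-geometry test. A point is inside the geometry when it is inside
# at least one member polygon; within a polygon the even-odd rule over all
# of its rings applies (so holes are excluded). Uses the half-open
# crossing-number convention, robust against rays through vertices.
pt_in_geom <- function(edges, px, py) {
  if (nrow(edges) == 0L) return(FALSE)
  y1 <- edges[, "y1"]; y2 <- edges[, "y2"]
  cross <- (y1 > py) != (y2 > py)
  if (!any(cross)) return(FALSE)
  e <- edges[cross, , drop = FALSE]
  xat <- e[, "x1"] + (py - e[, "y1"]) / (e[, "y2"] - e[, "y1"]) *
    (e[, "x2"] - e[, "x1"])
  hit <- xat > px
  if (!any(hit)) return(FALSE)
  counts <- tapply(hit, e[, "poly"], sum)
  any(counts %% 2L == 1L)
}

# Signed shoelace area of one ring (input units squared).
ring_signed_area <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  n <- length(x)
  nxt <- c(2:n, 1L)
  0.5 * sum(x * y[nxt] - x[nxt] * y)
}

# Planar area of a geometry: |exterior| minus |holes| per polygon, summed.
# Member polygons are assumed interior-disjoint (true for all overlay
# products in this package).
geom_area_planar <- function(g) {
  if (geom_is_empty(g)) return(0)
  sum(vapply(g, function(p) {
    a <- abs(ring_signed_area(p[[1L]]))
    if (length(p) > 1L)
      a <- a - sum(vapply(p[-1L], function(r) abs(ring_signed_area(r)), 0))
    max(a, 0)
  }, 0))
}

# Interior x-coordinates of proper crossings between any two edges.
# Endpoint-on-edge contacts are already covered by vertex breakpoints.
edge_crossing_x <- function(edges) {
  m <- nrow(edges)
  if (m < 2L) return(numeric(0))
  # bbox prefilter on pairs
  xlo <- pmin(edges[, "x1"], edges[, "x2"])
  xhi <- pmax(edges[, "x1"], edges[, "x2"])
  ylo <- pmin(edges[, "y1"], edges[, "y2"])
  yhi <- pmax(edges[, "y1"], edges[, "y2"])
  pair <- which(
    outer(xlo, xhi, "<=") & outer(xhi, xlo, ">=") &
      outer(ylo, yhi, "<=") & outer(yhi, ylo, ">="),
    arr.ind = TRUE)
  pair <- pair[pair[, 1L] < pair[, 2L], , drop = FALSE]
  if (nrow(pair) == 0L) return(numeric(0))
  i <- pair[, 1L]; j <- pair[, 2L]
  p1x <- edges[i, "x1"]; p1y <- edges[i, "y1"]
  d1x <- edges[i, "x2"] - p1x; d1y <- edges[i, "y2"] - p1y
  q1x <- edges[j, "x1"]; q1y <- edges[j, "y1"]
  d2x <- edges[j, "x2"] - q1x; d2y <- edges[j, "y2"] - q1y
  den <- d1x * d2y - d1y * d2x
  rx <- q1x - p1x; ry <- q1y - p1y
  ok <- abs(den) > .Machine$double.eps * (abs(d1x * d2y) + abs(d1y * d2x) + 1)
  t <- (rx * d2y - ry * d2x) / den
  u <- (rx * d1y - ry * d1x) / den
  eps <- 1e-12
  ok <- ok & t > eps & t < 1 - eps & u > eps & u < 1 - eps
  if (!any(ok)) return(numeric(0))
  (p1x + t * d1x)[ok]
}
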