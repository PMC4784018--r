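# Random-geometry helpers shared across test files. All generators take the
# RNG as-is; tests wrap them in a fixed seed.

# random axis-aligned rectangle inside [lo, hi]^2
random_rect <- function(lo = 0, hi = 100, min_side = 1) {
  w <- runif(1, min_side, (hi - lo) / 4)
  h <- runif(1, min_side, (hi - lo) / 4)
  x <- runif(1, lo, hi - w)
  y <- runif(1, lo, hi - h)
  c(x, y, x + w, y + h)
}

# random convex polygon: n points on a jittered circle, sorted by angle
random_convex_poly <- function(cx, cy, r, n = 6L) {
  ang <- sort(runif(n, 0, 2 * pi))
  rad <- runif(n, 0.5 * r, r)
  est_geom(list(list(cbind(cx + rad * cos(ang), cy + rad * sin(ang)))))
}

# closed-form overlap area of two axis-aligned rectangles
rect_overlap_area <- function(a, b) {
  ox <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  oy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  ox * oy
}

# closed-form gap between two axis-aligned rectangles
rect_gap <- function(a, b) {
  dx <- max(0, b[1] - a[3], a[1] - b[3])
  dy <- max(0, b[2] - a[4], a[2] - b[4])
  sqrt(dx^2 + dy^2)
}

rect_geom <- function(r) geom_rect(r[1], r[2], r[3], r[4])

# l'Huilier spherical-triangle area, written out independently of the
# package's own oracle (unit-vector chords -> excess)
lhuilier_area_km2 <- function(p, R) {
  lam <- p[, 1] * pi / 180; phi <- p[, 2] * pi / 180
  v <- cbind(cos(phi) * cos(lam), cos(phi) * sin(lam), sin(phi))
  s <- function(i, j) 2 * asin(min(1, 0.5 * sqrt(sum((v[i, ] - v[j, ])^2))))
  a <- s(2, 3); b <- s(1, 3); cc <- s(1, 2)
  sp <- (a + b + cc) / 2
  4 * atan(sqrt(max(0, tan(sp / 2) * tan((sp - a) / 2) *
                      tan((sp - b) / 2) * tan((sp - cc) / 2)))) * R^2
}
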