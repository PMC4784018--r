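planar <- metric_config("planar")
sphere <- metric_config("spherical", ellipsoid = "sphere")
R_auth <- 6371.007181

test_that("planar areas: unit square, holes, degeneracy, invariances", {
  expect_equal(polygon_area_km2(geom_rect(0, 0, 1, 1), planar), 1)
  # hole subtraction
  holed <- est_geom(list(list(
    rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)),
    rbind(c(2, 2), c(4, 2), c(4, 4), c(2, 4)))))
  expect_equal(polygon_area_km2(holed, planar), 96)
  # collinear ring measures zero
  degen <- est_geom(list(list(rbind(c(0, 0), c(1, 1), c(2, 2)))))
  expect_equal(polygon_area_km2(degen, planar), 0)
  # ring orientation is normalised, not an error
  cw <- est_geom(list(list(rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0)))))
  expect_equal(polygon_area_km2(cw, planar), 1)
  set.seed(12)
  for (i in 1:10) {
    g <- random_convex_poly(runif(1, -5, 5), runif(1, -5, 5), runif(1, 1, 4))
    a0 <- polygon_area_km2(g, planar)
    shift <- runif(2, -100, 100)
    g2 <- est_geom(list(list(sweep(unclass(g)[[1]][[1]], 2, -shift))))
    expect_equal(polygon_area_km2(g2, planar), a0, tolerance = 1e-12)
  }
  # additivity over disjoint members
  both <- geom_combine(geom_rect(0, 0, 3, 2), geom_rect(10, 0, 11, 5))
  expect_equal(polygon_area_km2(both, planar), 11, tolerance = 1e-12)
})

test_that("geodesic areas match spherical-excess closed forms", {
  # octant of the sphere
  tri <- est_geom(list(list(rbind(c(0, 0), c(90, 0), c(0, 90)))))
  expect_equal(polygon_area_km2(tri, sphere), 4 * pi * R_auth^2 / 8,
               tolerance = 1e-12)
  set.seed(31)
  for (i in 1:25) {
    p <- cbind(runif(3, -90, 90), runif(3, -60, 60))
    e <- polygon_area_km2(est_geom(list(list(p))), sphere)
    expect_equal(e, lhuilier_area_km2(p, R_auth), tolerance = 1e-9)
    expect_equal(e, spherical_triangle_area_km2(p, R_auth), tolerance = 1e-9)
  }
})

test_that("antimeridian-spanning and out-of-range coordinates are rejected", {
  wide <- est_geom(list(list(rbind(c(-179, 0), c(179, 0), c(0, 10)))))
  expect_error(polygon_area_km2(wide, sphere), "antimeridian")
  bad <- est_geom(list(list(rbind(c(0, -95), c(1, 0), c(0, 1)))))
  expect_error(polygon_area_km2(bad, sphere), "latitude")
})

test_that("planar minimum distances are exact and symmetric", {
  a <- list(geom_rect(0, 0, 1, 1))
  b <- list(geom_rect(4, 0, 5, 1))
  expect_equal(min_patch_distance_km(a, b, planar), 3)
  expect_equal(min_patch_distance_km(b, a, planar), 3)
  # touching, overlapping, contained: all zero
  expect_equal(min_patch_distance_km(a, list(geom_rect(1, 0, 2, 1)), planar), 0)
  expect_equal(min_patch_distance_km(a, list(geom_rect(0.5, 0.5, 2, 2)), planar), 0)
  expect_equal(min_patch_distance_km(list(geom_rect(-1, -1, 3, 3)), a, planar), 0)
  # corner-touch is adjacency too
  expect_equal(min_patch_distance_km(a, list(geom_rect(1, 1, 2, 2)), planar), 0)
  # diagonal separation
  expect_equal(min_patch_distance_km(a, list(geom_rect(4, 5, 6, 7)), planar), 5)
  expect_error(min_patch_distance_km(list(), a, planar), "at least one patch")
})

test_that("brute-force oracle self-checks and bounds the engine", {
  a <- list(geom_rect(0, 0, 1, 1))
  b <- list(geom_rect(4, 0, 5, 1))
  expect_equal(brute_force_min_distance(a, b, 100, planar), 3, tolerance = 1e-6)
  expect_equal(brute_force_min_distance(a, list(geom_rect(0.5, 0, 2, 1)), 10,
                                        planar), 0)
  set.seed(77)
  for (i in 1:30) {
    g1 <- list(random_convex_poly(runif(1, 0, 3), runif(1, 0, 3), 0.5))
    g2 <- list(random_convex_poly(runif(1, 6, 9), runif(1, 6, 9), 0.5))
    eng <- min_patch_distance_km(g1, g2, planar)
    orc <- brute_force_min_distance(g1, g2, 60, planar)
    expect_gte(orc, eng - 1e-9)          # oracle upper-bounds the truth
    expect_lt(abs(eng - orc), max(1e-6, orc / 1e4) + 1e-3)
  }
})

test_that("geodesic distances: equatorial arc, touching cells, oracle agreement", {
  deg_km <- pi * R_auth / 180
  d <- min_patch_distance_km(list(geom_rect(0, 0, 0.1, 0.1)),
                             list(geom_rect(1.1, 0, 1.2, 0.1)), sphere)
  # meridian separation shrinks with latitude, so the closest boundary
  # points sit at the squares' top corners (lat 0.1), not on the equator
  expect_equal(d, deg_km * cos(0.1 * pi / 180), tolerance = 1e-6)
  expect_lte(d, deg_km)
  expect_equal(min_patch_distance_km(list(geom_rect(0, 0, 1, 1)),
                                     list(geom_rect(1, 0, 2, 1)), sphere), 0)
  set.seed(13)
  for (i in 1:8) {
    lat <- runif(1, -40, 40)
    g1 <- list(random_convex_poly(runif(1, 0, 0.5), lat, 0.3, n = 4))
    g2 <- list(random_convex_poly(runif(1, 2, 3), lat + runif(1, -1, 1), 0.3, n = 4))
    eng <- min_patch_distance_km(g1, g2, sphere)
    orc <- brute_force_min_distance(g1, g2, 200, sphere)
    expect_lt(abs(eng - orc) / orc, 1e-4)
  }
})
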