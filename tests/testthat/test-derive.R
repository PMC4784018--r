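planar <- metric_config("planar")

hotspot_tbl <- function(...) {
  gs <- list(...)
  tibble::tibble(id = sprintf("h%d", seq_along(gs)), geometry = gs)
}
degr_tbl <- function(geoms, cats) {
  tibble::tibble(id = sprintf("d%d", seq_along(geoms)), geometry = geoms,
                 category = as.integer(cats))
}

test_that("source derivation is the unstable-hotspot intersection", {
  unstable <- geom_rect(0, 0, 10, 10)
  # hotspot fully containing the unstable region: identity
  src <- derive_source(unstable, hotspot_tbl(geom_rect(-5, -5, 20, 20)))
  expect_equal(polygon_area_km2(src$geometry), 100, tolerance = 1e-12)
  # disjoint: empty
  src <- derive_source(unstable, hotspot_tbl(geom_rect(50, 50, 60, 60)))
  expect_true(geom_is_empty(src$geometry))
  # hotspot over the right half of a unit square
  src <- derive_source(geom_rect(0, 0, 1, 1), hotspot_tbl(geom_rect(0.5, -1, 2, 2)))
  expect_equal(polygon_area_km2(src$geometry), 0.5, tolerance = 1e-12)
  expect_equal(src$role, "source")
})

test_that("receptor derivation uses only degradation categories 3 and 4", {
  stable <- geom_rect(0, 0, 10, 10)
  # category 1-2 contribute nothing
  rec <- derive_receptor(stable, degr_tbl(list(geom_rect(1, 1, 9, 9)), 2))
  expect_true(geom_is_empty(rec$geometry))
  # category 4 polygon fully inside the stable region: identity
  rec <- derive_receptor(stable, degr_tbl(list(geom_rect(2, 2, 5, 5)), 4))
  expect_equal(polygon_area_km2(rec$geometry), 9, tolerance = 1e-12)
  # mixed categories: only the severe ones count
  rec <- derive_receptor(stable, degr_tbl(
    list(geom_rect(0, 0, 2, 2), geom_rect(5, 5, 7, 7), geom_rect(8, 8, 9, 9)),
    c(1, 3, 4)))
  expect_equal(polygon_area_km2(rec$geometry), 5, tolerance = 1e-12)
  expect_error(derive_receptor(stable, degr_tbl(list(geom_rect(0, 0, 1, 1)), 5)),
               "1..4")
})

test_that("derived layers are subsets of both operands and idempotent", {
  set.seed(23)
  for (i in 1:10) {
    unstable <- geom_combine(rect_geom(random_rect()), rect_geom(random_rect()))
    hs <- hotspot_tbl(rect_geom(random_rect()), rect_geom(random_rect()))
    src <- derive_source(unstable, hs)$geometry
    a <- polygon_area_km2(src)
    # containment: intersecting back with each operand changes nothing
    expect_equal(polygon_area_km2(geom_intersection(src, unstable)), a,
                 tolerance = 1e-9)
    expect_equal(polygon_area_km2(geom_intersection(src, geom_combine(hs$geometry))),
                 a, tolerance = 1e-9)
    # idempotence
    expect_equal(polygon_area_km2(derive_source(unstable, hs)$geometry), a)
  }
})

test_that("country clipping conserves area and splits patches correctly", {
  countries <- tibble::tibble(
    iso3 = c("AAA", "BBB"), name = c("Alpha", "Beta"),
    geometry = list(geom_rect(0, 0, 100, 100), geom_rect(100, 0, 200, 100)))
  # a rectangle straddling the border: one patch per country, areas conserved
  layer <- structure(list(role = "source",
                          geometry = geom_intersection(geom_rect(80, 10, 120, 30),
                                                       geom_rect(80, 10, 120, 30))),
                     class = "derived_layer")
  p <- clip_to_countries(layer, countries, planar)
  expect_equal(nrow(p), 2)
  expect_setequal(p$iso3, c("AAA", "BBB"))
  expect_equal(sum(p$area_km2), 40 * 20, tolerance = 1e-9)
  expect_equal(p$area_km2[p$iso3 == "AAA"], 20 * 20, tolerance = 1e-9)
  # a layer entirely inside one country keeps its iso3
  layer2 <- structure(list(role = "receptor", geometry = geom_rect(10, 10, 20, 20)),
                      class = "derived_layer")
  p2 <- clip_to_countries(layer2, countries, planar)
  expect_equal(p2$iso3, "AAA")
  # disconnected pieces become separate patches
  layer3 <- structure(list(role = "source",
                           geometry = geom_combine(geom_rect(10, 10, 20, 20),
                                                   geom_rect(40, 40, 50, 50))),
                      class = "derived_layer")
  p3 <- clip_to_countries(layer3, countries, planar)
  expect_equal(nrow(p3), 2)
  expect_true(all(p3$area_km2 == 100))
  # empty layer, and layer outside every country: no patches
  empty <- structure(list(role = "source", geometry = est_geom()),
                     class = "derived_layer")
  expect_equal(nrow(clip_to_countries(empty, countries, planar)), 0)
  ocean <- structure(list(role = "source", geometry = geom_rect(500, 500, 600, 600)),
                     class = "derived_layer")
  expect_equal(nrow(clip_to_countries(ocean, countries, planar)), 0)
})
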