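test_that("rectangle overlays match closed-form areas", {
  set.seed(101)
  for (i in 1:40) {
    a <- random_rect(); b <- random_rect()
    ga <- rect_geom(a); gb <- rect_geom(b)
    aa <- (a[3] - a[1]) * (a[4] - a[2])
    ab <- (b[3] - b[1]) * (b[4] - b[2])
    ov <- rect_overlap_area(a, b)
    expect_equal(polygon_area_km2(geom_intersection(ga, gb)), ov, tolerance = 1e-12)
    expect_equal(polygon_area_km2(geom_union(ga, gb)), aa + ab - ov,
                 tolerance = 1e-12)
    expect_equal(polygon_area_km2(geom_overlay(ga, gb, "difference")), aa - ov,
                 tolerance = 1e-12)
  }
})

test_that("coverage semantics: overlapping members are never double-counted", {
  set.seed(7)
  for (i in 1:10) {
    a <- random_rect(); b <- random_rect(); c <- random_rect()
    g <- geom_combine(rect_geom(a), rect_geom(b), rect_geom(c))
    # inclusion-exclusion over three rectangles
    pairwise <- rect_overlap_area(a, b) + rect_overlap_area(a, c) +
      rect_overlap_area(b, c)
    triple_rect <- c(max(a[1], b[1], c[1]), max(a[2], b[2], c[2]),
                     min(a[3], b[3], c[3]), min(a[4], b[4], c[4]))
    triple <- max(0, triple_rect[3] - triple_rect[1]) *
      max(0, triple_rect[4] - triple_rect[2])
    truth <- sum((c(a[3], b[3], c[3]) - c(a[1], b[1], c[1])) *
                 (c(a[4], b[4], c[4]) - c(a[2], b[2], c[2]))) -
      pairwise + triple
    expect_equal(polygon_area_km2(geom_dissolve(g)), truth, tolerance = 1e-12)
  }
})

test_that("overlay agrees with an independent geometry library on random polygons", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  set.seed(55)
  cases <- lapply(1:12, function(i) {
    a <- random_convex_poly(runif(1, 30, 70), runif(1, 30, 70), runif(1, 10, 25))
    b <- random_convex_poly(runif(1, 30, 70), runif(1, 30, 70), runif(1, 10, 25))
    list(a = unclass(a)[[1]][[1]], b = unclass(b)[[1]][[1]])
  })
  inp <- tempfile(fileext = ".json")
  jsonlite::write_json(lapply(cases, function(cs)
    list(a = cs$a, b = cs$b)), inp, digits = NA)
  py <- tempfile(fileext = ".py")
  writeLines(c(
    "import json, sys",
    "from shapely.geometry import Polygon",
    "cases = json.load(open(sys.argv[1]))",
    "out = []",
    "for c in cases:",
    "    A = Polygon(c['a']); B = Polygon(c['b'])",
    "    out.append({'i': A.intersection(B).area, 'u': A.union(B).area,",
    "                'd': A.distance(B)})",
    "print(json.dumps(out))"), py)
  res <- jsonlite::fromJSON(system2("python", c(py, inp), stdout = TRUE))
  for (k in seq_along(cases)) {
    ga <- est_geom(list(list(cases[[k]]$a)))
    gb <- est_geom(list(list(cases[[k]]$b)))
    expect_equal(polygon_area_km2(geom_intersection(ga, gb)), res$i[k],
                 tolerance = 1e-9)
    expect_equal(polygon_area_km2(geom_union(ga, gb)), res$u[k],
                 tolerance = 1e-9)
    expect_equal(min_patch_distance_km(list(ga), list(gb),
                                       metric_config("planar")),
                 res$d[k], tolerance = 1e-9)
  }
})

test_that("connected components follow the edge-sharing convention", {
  # disjoint squares: two components
  u <- geom_union(geom_rect(0, 0, 1, 1), geom_rect(2, 0, 3, 1))
  expect_equal(max(geom_components(u)), 2)
  # edge-sharing squares: one component
  u <- geom_union(geom_rect(0, 0, 1, 1), geom_rect(1, 0, 2, 1))
  expect_equal(max(geom_components(u)), 1)
  # point-touching squares: separate components
  u <- geom_union(geom_rect(0, 0, 1, 1), geom_rect(1, 1, 2, 2))
  expect_equal(max(geom_components(u)), 2)
  # L-shape plus separate square
  u <- geom_union(geom_combine(geom_rect(0, 0, 2, 1), geom_rect(0, 1, 1, 2)),
                  geom_rect(5, 5, 6, 6))
  lab <- geom_components(u)
  expect_equal(max(lab), 2)
  areas <- vapply(split(seq_along(lab), lab), function(ix) {
    sub <- est_geom(unclass(u)[ix]); geom_is_empty(sub); polygon_area_km2(sub)
  }, 0)
  expect_setequal(round(sort(areas), 9), c(1, 3))
})

test_that("overlay is idempotent and empty-safe", {
  g <- geom_intersection(geom_rect(0, 0, 10, 7), geom_rect(3, 2, 14, 9))
  g2 <- geom_intersection(g, g)
  expect_equal(polygon_area_km2(g2), polygon_area_km2(g), tolerance = 1e-12)
  expect_true(geom_is_empty(geom_intersection(est_geom(), geom_rect(0, 0, 1, 1))))
  expect_equal(polygon_area_km2(geom_union(est_geom(), geom_rect(0, 0, 1, 1))), 1)
})

test_that("self-intersecting rings are repaired by even-odd reconstruction", {
  # bowtie: crosses itself at (1, 1); even-odd interior = two unit triangles
  bow <- est_geom(list(list(rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2)))))
  fixed <- geom_dissolve(bow)
  expect_equal(polygon_area_km2(fixed), 2, tolerance = 1e-12)
})
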