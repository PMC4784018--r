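test_that("classify_country reproduces published worked examples", {
  # Turkey-like: all thresholds passed
  r <- classify_country(225564, 99797, 0)
  expect_false(any(r$source_limiting, r$receptor_limiting, r$distance_limiting))
  expect_equal(r$category, "best")
  # Australia-like: only distance limiting
  r <- classify_country(25241, 77190, 895)
  expect_equal(unlist(r[1, 1:3], use.names = FALSE), c(FALSE, FALSE, TRUE))
  expect_equal(r$category, "distance_limited")
  # Cambodia-like: only receptor limiting
  r <- classify_country(31448, 13063, 0)
  expect_equal(unlist(r[1, 1:3], use.names = FALSE), c(FALSE, TRUE, FALSE))
  expect_equal(r$category, "receptor_limited")
  # Georgia-like: source and receptor limiting
  r <- classify_country(13127, 3720, 0)
  expect_equal(unlist(r[1, 1:3], use.names = FALSE), c(TRUE, TRUE, FALSE))
  expect_equal(r$category, "multiple_limited")
  expect_error(classify_country(-1, 1, 1), "non-negative")
})

test_that("thresholds are sharp: equality counts as limiting", {
  r <- classify_country(15000, 20000, 100)
  expect_true(r$source_limiting)
  r <- classify_country(20000, 15000, 100)
  expect_true(r$receptor_limiting)
  r <- classify_country(20000, 20000, 500)
  expect_true(r$distance_limiting)
  # just past the thresholds: clean
  r <- classify_country(15000.001, 15000.001, 499.999)
  expect_equal(r$category, "best")
})

test_that("category never worsens as areas grow or distance shrinks", {
  set.seed(41)
  cat_rank <- function(x) match(x, c("best", "distance_limited",
                                     "receptor_limited", "source_limited",
                                     "multiple_limited"))
  for (i in 1:100) {
    s <- runif(1, 0, 40000); r <- runif(1, 0, 40000); d <- runif(1, 0, 1200)
    # improving a value can change which single factor limits, but can
    # never add a limiting factor or demote best to flagged
    nflags <- function(s., r., d.) sum(unlist(classify_country(s., r., d.)[1, 1:3]))
    expect_lte(nflags(s + runif(1, 0, 2e4), r, d), nflags(s, r, d))
    expect_lte(nflags(s, r + runif(1, 0, 2e4), d), nflags(s, r, d))
    expect_lte(nflags(s, r, d * runif(1)), nflags(s, r, d))
    if (classify_country(s, r, d)$category == "best")
      expect_equal(classify_country(s + 1, r + 1, max(0, d - 1))$category, "best")
    expect_true(cat_rank(classify_country(s, r, d)$category) %in% 1:5)
  }
})

test_that("the full published table classifies to its printed bold pattern", {
  ref <- reference_country_summaries()
  expect_equal(nrow(ref), 39)
  got <- classify_country(ref$source_area_1e3km2 * 1000,
                          ref$receptor_area_1e3km2 * 1000,
                          ref$min_dist_km)
  expect_equal(got$source_limiting, ref$source_limiting)
  expect_equal(got$receptor_limiting, ref$receptor_limiting)
  expect_equal(got$distance_limiting, ref$distance_limiting)
  expect_equal(sum(got$category == "best"), 11)
  # ranking puts every best-row before every flagged row
  tab <- cbind(tibble::tibble(iso3 = ref$country, name = ref$country,
                              source_area_1e3km2 = ref$source_area_1e3km2,
                              receptor_area_1e3km2 = ref$receptor_area_1e3km2,
                              min_dist_km = ref$min_dist_km), got)
  ranked <- rank_table(tab)
  expect_equal(ranked$rank, 1:39)
  expect_true(all(which(ranked$category == "best") <=
                  sum(ranked$category == "best")))
  expect_equal(ranked$name[1], "Turkey")
})

test_that("ties are broken deterministically and alphabetically", {
  base <- tibble::tibble(
    iso3 = c("BBB", "AAA"), name = c("Beta", "Alpha"),
    source_area_1e3km2 = 20, receptor_area_1e3km2 = 20, min_dist_km = 10)
  tab <- cbind(base, classify_country(20000, 20000, c(10, 10)))
  ranked <- rank_table(tab)
  expect_equal(ranked$name, c("Alpha", "Beta"))
})

test_that("summarize_country aggregates patches and applies the adjacency rule", {
  planar <- metric_config("planar")
  patches <- tibble::tibble(
    iso3 = "AAA",
    role = c("source", "receptor"),
    geometry = list(geom_rect(0, 0, 10, 10), geom_rect(20, 0, 25, 5)),
    area_km2 = c(100, 25))
  s <- summarize_country(patches, planar)
  expect_equal(s$source_area_1e3km2, 0.100)
  expect_equal(s$receptor_area_1e3km2, 0.025)
  expect_equal(s$min_dist_km, 10)
  # overlapping source and receptor: distance 0
  patches$geometry[[2]] <- geom_rect(5, 5, 15, 15)
  expect_equal(summarize_country(patches, planar)$min_dist_km, 0)
  expect_error(summarize_country(patches[1, ], planar), "lacks patches")
})
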