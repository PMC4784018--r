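#' Parameters for synthetic world generation
#'
#' Defines a synthetic input world: a grid of rectangular countries, each
#' tiled by a k-by-k grid of rectangular ecoregions carrying seven scenario
#' stability indices, with hotspot and soil-degradation polygons planted on
#' known cells so that every downstream quantity (per-country areas, minimum
#' distances, categories) has an analytically known ground truth.
#'
#' In planar mode countries are 1000 x 1000 km squares on an abstract km
#' plane; in spherical mode they are 8 x 8 degree lon/lat cells centred on
#' the equator, measured on an authalic Earth sphere (so planted areas have
#' the closed lat-band form).
#'
#' Scenario indices are drawn as the cell's class mean plus per-scenario
#' noise truncated at three standard deviations; class means keep a 3-sigma
#' margin from the 0.33/0.66 thresholds, so planted classifications are
#' noise-proof by construction.
#'
#' @param seed integer; fully determines the world.
#' @param n_countries number of countries (>= 1).
#' @param country_grid integer `c(rows, cols)` layout; `rows * cols` must be
#'   >= `n_countries` (and `rows <= 10` in spherical mode so the window stays
#'   within +-40 degrees latitude).
#' @param cells_per_country k: each country is tiled k x k by ecoregions.
#' @param frac_unstable,frac_stable proportions of each country's cells given
#'   unstable / stable mean indices (sum <= 1; the rest are intermediate).
#' @param hotspot_coverage proportion of unstable cells that receive a
#'   planted hotspot (these become source area).
#' @param degraded_coverage proportion of stable cells that receive a
#'   planted category-3/4 degradation polygon (these become receptor area).
#' @param index_noise_sd per-scenario jitter SD (<= 0.04 so that 3-sigma
#'   margins from both thresholds remain feasible).
#' @param mode `"planar"` or `"spherical"`.
#' @return A list of class `world_params`.
#' @export
world_params <- function(seed = 1L,
                         n_countries = 4L,
                         country_grid = c(2L, 2L),
                         cells_per_country = 4L,
                         frac_unstable = 0.25,
                         frac_stable = 0.25,
                         hotspot_coverage = 0.6,
                         degraded_coverage = 0.6,
                         index_noise_sd = 0.02,
                         mode = c("planar", "spherical")) {
  mode <- match.arg(mode)
  props <- c(frac_unstable = frac_unstable, frac_stable = frac_stable,
             hotspot_coverage = hotspot_coverage,
             degraded_coverage = degraded_coverage)
  if (any(props < 0 | props > 1))
    stop("proportions must lie in [0, 1]")
  if (frac_unstable + frac_stable > 1)
    stop("infeasible coverage fractions: frac_unstable + frac_stable > 1")
  if (index_noise_sd < 0 || index_noise_sd > 0.04)
    stop("infeasible index_noise_sd: 3-sigma margins from the 0.33/0.66 ",
         "thresholds require index_noise_sd in [0, 0.04]")
  stopifnot(n_countries >= 1, length(country_grid) == 2L,
            prod(country_grid) >= n_countries, cells_per_country >= 1)
  if (mode == "spherical" && country_grid[1L] > 10L)
    stop("spherical worlds support at most 10 grid rows (latitude window)")
  structure(list(seed = as.integer(seed), n_countries = as.integer(n_countries),
                 country_grid = as.integer(country_grid),
                 cells_per_country = as.integer(cells_per_country),
                 frac_unstable = frac_unstable, frac_stable = frac_stable,
                 hotspot_coverage = hotspot_coverage,
                 degraded_coverage = degraded_coverage,
                 index_noise_sd = index_noise_sd, mode = mode),
            class = "world_params")
}

# sample() that never falls into the 1:x trap
resample <- function(x, size) x[sample.int(length(x), size)]

with_preserved_seed <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

#' Spherical-excess triangle area oracle
#'
#' Closed-form area of a spherical triangle with great-circle edges, by
#' l'Huilier's theorem. Independent of the geodesic area engine; used to
#' compute synthetic ground truth and to cross-check [polygon_area_km2()].
#'
#' @param p 3 x 2 matrix of lon/lat vertices, degrees.
#' @param radius_km sphere radius in km (default authalic Earth radius).
#' @return Area in km^2.
#' @export
spherical_triangle_area_km2 <- function(p, radius_km = 6371.007181) {
  stopifnot(is.matrix(p), nrow(p) == 3L, ncol(p) == 2L)
  lam <- p[, 1L] * pi / 180; phi <- p[, 2L] * pi / 180
  v <- cbind(cos(phi) * cos(lam), cos(phi) * sin(lam), sin(phi))
  side <- function(i, j) 2 * asin(pmin(1, 0.5 * sqrt(sum((v[i, ] - v[j, ])^2))))
  a <- side(2L, 3L); b <- side(1L, 3L); cc <- side(1L, 2L)
  s <- (a + b + cc) / 2
  t <- tan(s / 2) * tan((s - a) / 2) * tan((s - b) / 2) * tan((s - cc) / 2)
  4 * atan(sqrt(max(t, 0))) * radius_km^2
}

# closed-form area of an axis-aligned rectangle, km^2; the spherical value
# reads the four corners as a great-circle quadrilateral, split into two
# spherical-excess triangles
rect_area_km2 <- function(r, mode, ellipsoid = NULL) {
  if (mode == "planar") return((r[3L] - r[1L]) * (r[4L] - r[2L]))
  R <- ellipsoid$a / 1000
  sw <- c(r[1L], r[2L]); se <- c(r[3L], r[2L])
  ne <- c(r[3L], r[4L]); nw <- c(r[1L], r[4L])
  spherical_triangle_area_km2(rbind(sw, se, ne), R) +
    spherical_triangle_area_km2(rbind(sw, ne, nw), R)
}

# closed-form distance between two axis-aligned planar rectangles, km
rect_dist_planar <- function(r1, r2) {
  dx <- max(0, r2[1L] - r1[3L], r1[1L] - r2[3L])
  dy <- max(0, r2[2L] - r1[4L], r1[2L] - r2[4L])
  sqrt(dx * dx + dy * dy)
}

rects_touch <- function(r1, r2) {
  r2[1L] <= r1[3L] && r1[1L] <= r2[3L] && r2[2L] <= r1[4L] && r1[2L] <= r2[4L]
}

# minimum distance between planted rectangle sets, km; spherical distances
# come from the boundary-sampling geodesic oracle (pairs pruned by a
# conservative equirectangular bound)
planted_min_dist_km <- function(src_rects, rec_rects, mode, ellipsoid) {
  if (mode == "planar") {
    return(min(vapply(src_rects, function(s)
      min(vapply(rec_rects, function(r) rect_dist_planar(s, r), 0)), 0)))
  }
  if (any(vapply(src_rects, function(s)
    any(vapply(rec_rects, function(r) rects_touch(s, r), TRUE)), TRUE)))
    return(0)
  R <- ellipsoid$a / 1000
  deg <- pi / 180 * R
  approx_d <- function(s, r) {
    dlat <- max(0, r[2L] - s[4L], s[2L] - r[4L])
    dlon <- max(0, r[1L] - s[3L], s[1L] - r[3L])
    # cos factor at the latitude nearest the equator is an upper bound on
    # the metric scale of the lon gap; using it keeps this a usable bound
    clat <- cos(min(abs(c(s[2L], s[4L], r[2L], r[4L]))) * pi / 180)
    deg * sqrt(dlat^2 + (dlon * clat)^2)
  }
  pairs <- expand.grid(i = seq_along(src_rects), j = seq_along(rec_rects))
  ad <- mapply(function(i, j) approx_d(src_rects[[i]], rec_rects[[j]]),
               pairs$i, pairs$j)
  keep <- which(ad <= min(ad) * 1.6 + 1)
  cfg <- metric_config("spherical", ellipsoid = ellipsoid)
  min(vapply(keep, function(k) {
    s <- src_rects[[pairs$i[k]]]; r <- rec_rects[[pairs$j[k]]]
    brute_force_min_distance(list(geom_rect(s[1L], s[2L], s[3L], s[4L])),
                             list(geom_rect(r[1L], r[2L], r[3L], r[4L])),
                             samples_per_edge = 200L, config = cfg)
  }, 0))
}

#' Generate a synthetic world fixture
#'
#' @param params a [world_params()].
#' @return A list of class `world_fixture`: `params`; `metric` (the
#'   [metric_config()] the fixture is measured in); tibbles `countries`
#'   (`iso3`, `name`, `geometry`), `ecoregions` (`id`, `geometry`,
#'   `stability`), `hotspots` (`id`, `geometry`), `degradation` (`id`,
#'   `geometry`, `category`); `planted` (per-country lists of planted source
#'   and receptor rectangles); and `truth`, the ranked per-country summary
#'   table computed from the planted rectangles by closed-form arithmetic
#'   (planar) or the geodesic sampling oracle (spherical), covering exactly
#'   the countries holding both roles.
#' @export
generate_world <- function(params = world_params()) {
  stopifnot(inherits(params, "world_params"))
  with_preserved_seed({
    set.seed(params$seed)
    mode <- params$mode
    ell <- if (mode == "planar") NULL else list(a = 6371007.181, f = 0)
    metric <- if (mode == "planar") metric_config("planar")
              else metric_config("spherical", ellipsoid = "sphere")
    rows <- params$country_grid[1L]; cols <- params$country_grid[2L]
    csize <- if (mode == "planar") 1000 else 8        # country edge
    k <- params$cells_per_country
    cs <- csize / k                                   # cell edge
    x_orig <- if (mode == "planar") 0 else -cols * csize / 2
    y_orig <- if (mode == "planar") 0 else -rows * csize / 2
    sd <- params$index_noise_sd

    draw_indices <- function(m) {
      noise <- pmin(pmax(stats::rnorm(7L, 0, sd), -3 * sd), 3 * sd)
      pmin(pmax(m + noise, 0), 1)
    }
    band_mean <- function(klass) {
      switch(klass,
        unstable = stats::runif(1L, max(0.02, 0.33 - 3 * sd - 0.15),
                                0.33 - 3 * sd - 0.005),
        stable = stats::runif(1L, 0.66 + 3 * sd + 0.005,
                              min(0.98, 0.66 + 3 * sd + 0.15)),
        stats::runif(1L, 0.45, 0.55))
    }
    # planted rectangles are cells shrunk by a margin that is an exact
    # binary fraction of the cell, keeping planar truth arithmetic exact
    draw_inset <- function() resample(c(0, 0, 2, 3, 4), 1L) / 16 * cs

    countries <- ecoregions <- hotspots <- degradation <- list()
    planted <- list()
    truth_rows <- list()
    for (ci in seq_len(params$n_countries)) {
      r <- (ci - 1L) %/% cols; cc <- (ci - 1L) %% cols
      cx0 <- x_orig + cc * csize; cy0 <- y_orig + r * csize
      iso <- sprintf("C%02d", ci)
      cname <- sprintf("Country %02d", ci)
      countries[[ci]] <- tibble::tibble(
        iso3 = iso, name = cname,
        geometry = list(geom_rect(cx0, cy0, cx0 + csize, cy0 + csize)))

      ncell <- k * k
      n_u <- round(params$frac_unstable * ncell)
      n_s <- round(params$frac_stable * ncell)
      picked <- resample(seq_len(ncell), n_u + n_s)
      u_cells <- picked[seq_len(n_u)]
      s_cells <- picked[setdiff(seq_len(n_u + n_s), seq_len(n_u))]
      klass <- rep("intermediate", ncell)
      klass[u_cells] <- "unstable"; klass[s_cells] <- "stable"

      cell_rect <- function(cell) {
        ix <- (cell - 1L) %% k; iy <- (cell - 1L) %/% k
        c(cx0 + ix * cs, cy0 + iy * cs, cx0 + (ix + 1L) * cs, cy0 + (iy + 1L) * cs)
      }
      for (cell in seq_len(ncell)) {
        rct <- cell_rect(cell)
        ecoregions[[length(ecoregions) + 1L]] <- tibble::tibble(
          id = sprintf("%s-E%02d", iso, cell),
          geometry = list(geom_rect(rct[1L], rct[2L], rct[3L], rct[4L])),
          stability = list(draw_indices(band_mean(klass[cell]))))
      }

      src_cells <- resample(u_cells, round(params$hotspot_coverage * n_u))
      rec_cells <- resample(s_cells, round(params$degraded_coverage * n_s))
      src_rects <- rec_rects <- list()
      for (cell in src_cells) {
        inset <- draw_inset()
        rct <- cell_rect(cell) + c(inset, inset, -inset, -inset)
        src_rects[[length(src_rects) + 1L]] <- rct
        hotspots[[length(hotspots) + 1L]] <- tibble::tibble(
          id = sprintf("%s-H%02d", iso, cell),
          geometry = list(geom_rect(rct[1L], rct[2L], rct[3L], rct[4L])))
      }
      for (cell in rec_cells) {
        inset <- draw_inset()
        rct <- cell_rect(cell) + c(inset, inset, -inset, -inset)
        rec_rects[[length(rec_rects) + 1L]] <- rct
        degradation[[length(degradation) + 1L]] <- tibble::tibble(
          id = sprintf("%s-D%02d", iso, cell),
          geometry = list(geom_rect(rct[1L], rct[2L], rct[3L], rct[4L])),
          category = resample(3:4, 1L))
      }

      # decoys that must not reach the derived layers: a hotspot over an
      # intermediate cell, mild (category 1-2) degradation over a stable
      # cell, and severe degradation over an intermediate cell
      inter_cells <- which(klass == "intermediate")
      if (length(inter_cells) >= 1L) {
        rct <- cell_rect(inter_cells[1L]) + c(cs / 8, cs / 8, -cs / 8, -cs / 8)
        hotspots[[length(hotspots) + 1L]] <- tibble::tibble(
          id = sprintf("%s-HX", iso),
          geometry = list(geom_rect(rct[1L], rct[2L], rct[3L], rct[4L])))
      }
      mild_cells <- setdiff(s_cells, rec_cells)
      if (length(mild_cells) >= 1L) {
        rct <- cell_rect(mild_cells[1L])
        degradation[[length(degradation) + 1L]] <- tibble::tibble(
          id = sprintf("%s-DX1", iso),
          geometry = list(geom_rect(rct[1L], rct[2L], rct[3L], rct[4L])),
          category = resample(1:2, 1L))
      }
      if (length(inter_cells) >= 2L) {
        rct <- cell_rect(inter_cells[2L]) + c(cs / 8, cs / 8, -cs / 8, -cs / 8)
        degradation[[length(degradation) + 1L]] <- tibble::tibble(
          id = sprintf("%s-DX2", iso),
          geometry = list(geom_rect(rct[1L], rct[2L], rct[3L], rct[4L])),
          category = 3L)
      }

      planted[[iso]] <- list(source = src_rects, receptor = rec_rects)
      if (length(src_rects) >= 1L && length(rec_rects) >= 1L) {
        sa <- sum(vapply(src_rects, rect_area_km2, 0, mode = mode, ellipsoid = ell))
        ra <- sum(vapply(rec_rects, rect_area_km2, 0, mode = mode, ellipsoid = ell))
        md <- planted_min_dist_km(src_rects, rec_rects, mode, ell)
        truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
          iso3 = iso, name = cname,
          source_area_1e3km2 = sa / 1000, receptor_area_1e3km2 = ra / 1000,
          min_dist_km = md)
      }
    }

    truth <- if (length(truth_rows)) {
      tr <- do.call(rbind, truth_rows)
      tr <- cbind(tr, classify_country(tr$source_area_1e3km2 * 1000,
                                       tr$receptor_area_1e3km2 * 1000,
                                       tr$min_dist_km))
      rank_table(tr)
    } else empty_summary_table()

    structure(list(
      params = params, metric = metric,
      countries = do.call(rbind, countries),
      ecoregions = do.call(rbind, ecoregions),
      hotspots = if (length(hotspots)) do.call(rbind, hotspots) else
        tibble::tibble(id = character(0), geometry = list()),
      degradation = if (length(degradation)) do.call(rbind, degradation) else
        tibble::tibble(id = character(0), geometry = list(), category = integer(0)),
      planted = planted, truth = truth), class = "world_fixture")
  })
}

#' Plant a fixture from explicit rectangles
#'
#' Low-level companion to [generate_world()]: builds a single-country world
#' holding exactly the given source and receptor rectangles. Each source
#' rectangle becomes an unstable ecoregion (constant indices 0.2) with a
#' hotspot over it; each receptor rectangle a stable ecoregion (constant
#' indices 0.8) with a category-3 degradation polygon. Ground truth follows
#' by rectangle arithmetic (planar) or the geodesic oracle (spherical).
#'
#' @param source_rects,receptor_rects lists of `c(xmin, ymin, xmax, ymax)`
#'   rectangles (km planar, degrees spherical). Must be mutually disjoint
#'   across roles.
#' @param country optional country rectangle; defaults to the bounding box
#'   of all planted rectangles padded by 10%.
#' @param mode `"planar"` or `"spherical"`.
#' @return A `world_fixture` (see [generate_world()]).
#' @export
plant_fixture <- function(source_rects, receptor_rects, country = NULL,
                          mode = c("planar", "spherical")) {
  mode <- match.arg(mode)
  ell <- if (mode == "planar") NULL else list(a = 6371007.181, f = 0)
  metric <- if (mode == "planar") metric_config("planar")
            else metric_config("spherical", ellipsoid = "sphere")
  allr <- c(source_rects, receptor_rects)
  stopifnot(length(source_rects) >= 1L, length(receptor_rects) >= 1L)
  if (is.null(country)) {
    m <- do.call(rbind, allr)
    pad <- 0.1 * max(m[, 3L] - m[, 1L], m[, 4L] - m[, 2L])
    country <- c(min(m[, 1L]) - pad, min(m[, 2L]) - pad,
                 max(m[, 3L]) + pad, max(m[, 4L]) + pad)
  }
  mk <- function(rects, prefix, level) {
    do.call(rbind, lapply(seq_along(rects), function(i) {
      r <- rects[[i]]
      tibble::tibble(id = sprintf("C01-%s%02d", prefix, i),
                     geometry = list(geom_rect(r[1L], r[2L], r[3L], r[4L])),
                     stability = list(rep(level, 7L)))
    }))
  }
  eco <- rbind(mk(source_rects, "E", 0.2), mk(receptor_rects, "E", 0.8))
  eco$id <- sprintf("C01-E%02d", seq_len(nrow(eco)))
  hs <- tibble::tibble(
    id = sprintf("C01-H%02d", seq_along(source_rects)),
    geometry = lapply(source_rects, function(r) geom_rect(r[1L], r[2L], r[3L], r[4L])))
  dg <- tibble::tibble(
    id = sprintf("C01-D%02d", seq_along(receptor_rects)),
    geometry = lapply(receptor_rects, function(r) geom_rect(r[1L], r[2L], r[3L], r[4L])),
    category = 3L)
  sa <- sum(vapply(source_rects, rect_area_km2, 0, mode = mode, ellipsoid = ell))
  ra <- sum(vapply(receptor_rects, rect_area_km2, 0, mode = mode, ellipsoid = ell))
  md <- planted_min_dist_km(source_rects, receptor_rects, mode, ell)
  tr <- tibble::tibble(iso3 = "C01", name = "Country 01",
                       source_area_1e3km2 = sa / 1000,
                       receptor_area_1e3km2 = ra / 1000, min_dist_km = md)
  tr <- cbind(tr, classify_country(tr$source_area_1e3km2 * 1000,
                                   tr$receptor_area_1e3km2 * 1000,
                                   tr$min_dist_km))
  structure(list(
    params = NULL, metric = metric,
    countries = tibble::tibble(iso3 = "C01", name = "Country 01",
                               geometry = list(geom_rect(country[1L], country[2L],
                                                         country[3L], country[4L]))),
    ecoregions = eco[, c("id", "geometry", "stability")],
    hotspots = hs, degradation = dg,
    planted = list(C01 = list(source = source_rects, receptor = receptor_rects)),
    truth = rank_table(tr)), class = "world_fixture")
}

#' @export
print.world_fixture <- function(x, ...) {
  cat(sprintf("<world_fixture: %d countries, %d ecoregions, %s mode, %d truth rows>\n",
              nrow(x$countries), nrow(x$ecoregions), x$metric$mode, nrow(x$truth)))
  invisible(x)
}
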