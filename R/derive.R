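#' Derive the candidate source layer
#'
#' Source areas are where low climatic stability coincides with high
#' conservation value: the geometric intersection of the unstable-ecoregion
#' union with the union of all biodiversity-hotspot polygons. Overlapping
#' hotspots are handled with coverage semantics (the overlay engine measures
#' the covered set, never double-counting), so no separate dissolve step is
#' needed.
#'
#' @param unstable `est_geom`, union of climatically unstable ecoregions.
#' @param hotspots tibble with a `geometry` list-column (hotspot polygons),
#'   or an `est_geom`.
#' @return List with `role = "source"` and `geometry` (an interior-disjoint
#'   `est_geom`, possibly empty).
#' @export
derive_source <- function(unstable, hotspots) {
  hs <- layer_geom(hotspots)
  structure(list(role = "source",
                 geometry = geom_intersection(unstable, hs)),
            class = "derived_layer")
}

#' Derive the candidate receptor layer
#'
#' Receptor areas are where high climatic stability coincides with severe
#' soil degradation: the intersection of the stable-ecoregion union with the
#' union of degradation polygons of severity categories 3 and 4 only;
#' categories 1 and 2 contribute nothing.
#'
#' @param stable `est_geom`, union of climatically stable ecoregions.
#' @param degradation tibble with `geometry` list-column and integer
#'   `category` column (values in 1..4).
#' @return List with `role = "receptor"` and `geometry` (an
#'   interior-disjoint `est_geom`, possibly empty).
#' @export
derive_receptor <- function(stable, degradation) {
  stopifnot(is.data.frame(degradation),
            all(c("geometry", "category") %in% names(degradation)))
  if (!all(degradation$category %in% 1:4))
    stop("degradation categories must be integers in 1..4")
  sel <- degradation$category %in% c(3L, 4L)
  dg <- if (any(sel)) geom_combine(degradation$geometry[sel]) else est_geom()
  structure(list(role = "receptor",
                 geometry = geom_intersection(stable, dg)),
            class = "derived_layer")
}

layer_geom <- function(x) {
  if (inherits(x, "est_geom")) return(x)
  if (inherits(x, "derived_layer")) return(x$geometry)
  if (is.data.frame(x) && "geometry" %in% names(x))
    return(if (nrow(x)) geom_combine(x$geometry) else est_geom())
  stop("cannot interpret object as a geometry layer")
}

#' @export
print.derived_layer <- function(x, ...) {
  cat(sprintf("<derived %s layer> ", x$role)); print(x$geometry); invisible(x)
}

#' Clip a derived layer to countries and extract patches
#'
#' Intersects a derived (source or receptor) layer with each country
#' boundary and splits the per-country result into connected components
#' ("patches"). Components sharing only a point are separate patches.
#' Any part of the layer outside every country is dropped.
#'
#' @param layer a `derived_layer` from [derive_source()]/[derive_receptor()],
#'   or an `est_geom` plus `role`.
#' @param countries tibble with columns `iso3`, `name`, `geometry`.
#' @param config a [metric_config()] used for patch areas.
#' @param role patch role when `layer` is a bare `est_geom`.
#' @return Tibble with columns `iso3`, `role`, `geometry` (list of
#'   `est_geom`, one connected component each) and `area_km2` (> 0).
#' @export
clip_to_countries <- function(layer, countries, config = metric_config(),
                              role = NULL) {
  if (inherits(layer, "derived_layer")) {
    role <- layer$role
    g <- layer$geometry
  } else {
    g <- layer
    if (is.null(role)) stop("role is required when layer is a bare geometry")
  }
  stopifnot(is.data.frame(countries),
            all(c("iso3", "geometry") %in% names(countries)))
  rows <- list()
  if (!geom_is_empty(g)) {
    for (ci in seq_len(nrow(countries))) {
      clipped <- geom_intersection(g, countries$geometry[[ci]])
      if (geom_is_empty(clipped)) next
      comp <- geom_components(clipped)
      sl <- attr(clipped, "slabs")
      for (cc in unique(comp)) {
        sub <- est_geom(unclass(clipped)[comp == cc])
        attr(sub, "slabs") <- sl[comp == cc, , drop = FALSE]
        a <- polygon_area_km2(sub, config)
        if (a <= 0) next
        rows[[length(rows) + 1L]] <-
          tibble::tibble(iso3 = countries$iso3[[ci]], role = role,
                         geometry = list(sub), area_km2 = a)
      }
    }
  }
  if (length(rows) == 0L)
    return(tibble::tibble(iso3 = character(0), role = character(0),
                          geometry = list(), area_km2 = numeric(0)))
  do.call(rbind, rows)
}
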