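#' Read a vector layer from GeoJSON
#'
#' Reads one of the four input layer kinds from a GeoJSON FeatureCollection
#' (RFC 7946 dialect: lon/lat axis order, WGS84; in planar worlds the same
#' container simply carries km coordinates). Every record is validated
#' against its layer invariants; invalid geometries are repaired once by
#' even-odd interior reconstruction (the zero-buffer-equivalent rule) and
#' rejected, naming the feature, if still empty.
#'
#' Expected properties by schema: `ecoregions` need `stability_s1` ..
#' `stability_s7`, each in \[0, 1\]; `degradation` needs integer `category`
#' in 1..4; `countries` need `iso3` (unique) and `name`; `hotspots` need
#' nothing beyond geometry. Property names can be remapped via `mapping`
#' (e.g. `mapping = list(iso3 = "ISO_A3")`).
#'
#' @param path GeoJSON file path.
#' @param schema one of `"ecoregions"`, `"hotspots"`, `"degradation"`,
#'   `"countries"`.
#' @param mapping optional named list mapping expected property names to the
#'   names used in the file.
#' @return A validated tibble with a `geometry` list-column of `est_geom`,
#'   plus the schema's attribute columns. An empty FeatureCollection yields
#'   an empty tibble.
#' @export
read_layer <- function(path, schema = c("ecoregions", "hotspots", "degradation", "countries"),
                       mapping = list()) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(fc$type) || fc$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection: ", path)
  feats <- fc$features
  if (length(feats) == 0L) return(empty_layer(schema))
  prop <- function(f, name, default = NULL) {
    key <- if (!is.null(mapping[[name]])) mapping[[name]] else name
    v <- f$properties[[key]]
    if (is.null(v)) default else v
  }
  rows <- lapply(seq_along(feats), function(i) {
    f <- feats[[i]]
    fid <- prop(f, "id", default = as.character(i))
    g <- parse_geojson_geometry(f$geometry, fid)
    g <- validate_geometry(g, fid)
    base <- tibble::tibble(id = as.character(fid), geometry = list(g))
    switch(schema,
      ecoregions = {
        s <- vapply(1:7, function(j) {
          v <- prop(f, sprintf("stability_s%d", j))
          if (is.null(v))
            stop("feature ", fid, ": missing required attribute stability_s", j)
          as.numeric(v)
        }, 0)
        if (anyNA(s) || any(s < 0 | s > 1))
          stop("feature ", fid, ": stability index outside [0, 1]")
        base$stability <- list(s)
        base
      },
      hotspots = base,
      degradation = {
        cat <- prop(f, "category")
        if (is.null(cat))
          stop("feature ", fid, ": missing required attribute category")
        cat <- as.integer(cat)
        if (is.na(cat) || !(cat %in% 1:4))
          stop("feature ", fid, ": category must be an integer in 1..4")
        base$category <- cat
        base
      },
      countries = {
        iso <- prop(f, "iso3")
        if (is.null(iso))
          stop("feature ", fid, ": missing required attribute iso3")
        tibble::tibble(iso3 = as.character(iso),
                       name = as.character(prop(f, "name", default = iso)),
                       geometry = list(g))
      })
  })
  out <- do.call(rbind, rows)
  if (schema == "countries" && anyDuplicated(out$iso3))
    stop("duplicate iso3 codes in country layer")
  out
}

empty_layer <- function(schema) {
  switch(schema,
    ecoregions = tibble::tibble(id = character(0), geometry = list(),
                                stability = list()),
    hotspots = tibble::tibble(id = character(0), geometry = list()),
    degradation = tibble::tibble(id = character(0), geometry = list(),
                                 category = integer(0)),
    countries = tibble::tibble(iso3 = character(0), name = character(0),
                               geometry = list()))
}

parse_geojson_geometry <- function(geom, fid) {
  if (is.null(geom$type)) stop("feature ", fid, ": missing geometry")
  ring_mat <- function(ring) do.call(rbind, lapply(ring, function(p)
    c(as.numeric(p[[1L]]), as.numeric(p[[2L]]))))
  switch(geom$type,
    Polygon = est_geom(list(lapply(geom$coordinates, ring_mat))),
    MultiPolygon = est_geom(lapply(geom$coordinates, function(poly)
      lapply(poly, ring_mat))),
    stop("feature ", fid, ": unsupported geometry type ", geom$type))
}

# One repair pass by even-odd interior reconstruction when a ring
# self-intersects; reject (naming the feature) if nothing remains.
validate_geometry <- function(g, fid) {
  e <- geom_edges(g)
  if (nrow(e) == 0L) stop("feature ", fid, ": empty geometry")
  per_poly_cross <- any(vapply(seq_along(g), function(ip) {
    ep <- e[e[, "poly"] == ip, , drop = FALSE]
    length(edge_crossing_x(ep)) > 0L
  }, TRUE))
  if (!per_poly_cross) return(g)
  repaired <- geom_dissolve(g)
  if (geom_is_empty(repaired))
    stop("feature ", fid, ": invalid geometry could not be repaired")
  repaired
}

geojson_geometry <- function(g) {
  close_ring <- function(r) rbind(r, r[1L, , drop = FALSE])
  coords <- lapply(unclass(g), function(p) lapply(p, close_ring))
  if (length(coords) == 1L)
    list(type = "Polygon", coordinates = coords[[1L]])
  else
    list(type = "MultiPolygon", coordinates = coords)
}

#' Write a vector layer to GeoJSON
#'
#' Inverse of [read_layer()]: writes a layer tibble as a GeoJSON
#' FeatureCollection with the schema's property names
#' (`stability_s1..s7`, `category`, `iso3`/`name`).
#'
#' @param layer layer tibble (see [read_layer()] return value).
#' @param path output file path.
#' @param schema layer kind, as in [read_layer()].
#' @return `path`, invisibly.
#' @export
write_layer <- function(layer, path,
                        schema = c("ecoregions", "hotspots", "degradation", "countries")) {
  schema <- match.arg(schema)
  feats <- lapply(seq_len(nrow(layer)), function(i) {
    props <- switch(schema,
      ecoregions = {
        s <- as.list(layer$stability[[i]])
        names(s) <- sprintf("stability_s%d", 1:7)
        c(list(id = layer$id[[i]]), s)
      },
      hotspots = list(id = layer$id[[i]]),
      degradation = list(id = layer$id[[i]],
                         category = as.integer(layer$category[[i]])),
      countries = list(iso3 = layer$iso3[[i]], name = layer$name[[i]]))
    list(type = "Feature", properties = props,
         geometry = geojson_geometry(layer$geometry[[i]]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Write the ranked country summary table as CSV
#'
#' Mirrors the published table conventions: areas in thousands of km^2
#' printed with 3 decimals, distances as whole km. Input rows must already
#' be ranked (a non-missing `rank` column).
#'
#' @param rows ranked summary tibble ([rank_countries()] output).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(rows, path) {
  cols <- c("source_area_1e3km2", "receptor_area_1e3km2", "min_dist_km",
            "source_limiting", "receptor_limiting", "distance_limiting",
            "category")
  stopifnot(is.data.frame(rows), all(cols %in% names(rows)))
  if (is.null(rows[["rank"]]) || anyNA(rows[["rank"]]))
    stop("rows must be ranked before writing (missing rank)")
  header <- paste(c("country", cols, "rank"), collapse = ",")
  lines <- header
  if (nrow(rows) > 0L) {
    country <- if (!is.null(rows[["name"]])) rows[["name"]] else rows[["iso3"]]
    quoted <- ifelse(grepl("[,\"]", country),
                     paste0('"', gsub('"', '""', country), '"'), country)
    lines <- c(lines, paste(
      quoted,
      sprintf("%.3f", rows$source_area_1e3km2),
      sprintf("%.3f", rows$receptor_area_1e3km2),
      sprintf("%d", as.integer(round(rows$min_dist_km))),
      rows$source_limiting, rows$receptor_limiting, rows$distance_limiting,
      rows$category, rows$rank, sep = ","))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a summary table written by [write_summary_table()]
#' @param path CSV path.
#' @return Tibble with typed columns (`country`, areas, distance, flags,
#'   `category`, `rank`).
#' @export
read_summary_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (fl in c("source_limiting", "receptor_limiting", "distance_limiting"))
    df[[fl]] <- as.logical(df[[fl]])
  tibble::as_tibble(df)
}

#' Export a synthetic world fixture to disk
#'
#' Writes the four layers as GeoJSON (`ecoregions.geojson`,
#' `hotspots.geojson`, `degradation.geojson`, `countries.geojson`) and the
#' ground-truth summary as `truth.csv` into `dir`.
#'
#' @param world a `world_fixture` from [generate_world()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "world_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_layer(world$ecoregions, file.path(dir, "ecoregions.geojson"), "ecoregions")
  write_layer(world$hotspots, file.path(dir, "hotspots.geojson"), "hotspots")
  write_layer(world$degradation, file.path(dir, "degradation.geojson"), "degradation")
  write_layer(world$countries, file.path(dir, "countries.geojson"), "countries")
  write_summary_table(world$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}
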