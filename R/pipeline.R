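#' Pipeline configuration
#'
#' One configuration object drives a full run: either a synthetic world
#' (`simulate`) or paths to the four input layers (`layers`), the stability
#' thresholds, the metric and ranking settings, and an optional output
#' directory. Can be read from YAML.
#'
#' @param simulate `NULL`, or a list of [world_params()] arguments (the
#'   pipeline seed is injected as the world seed).
#' @param layers `NULL`, or a named list with paths `ecoregions`,
#'   `hotspots`, `degradation`, `countries` (GeoJSON).
#' @param tau_unstable,tau_stable stability thresholds; must satisfy
#'   `tau_unstable < tau_stable`.
#' @param metric a [metric_config()] or a list of its arguments.
#' @param ranking a [ranking_config()] or a list of its arguments.
#' @param out_dir optional output directory; when set, all stage outputs are
#'   written there.
#' @param seed integer seed for all randomness in the run.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, layers = NULL,
                            tau_unstable = 0.33, tau_stable = 0.66,
                            metric = metric_config(), ranking = ranking_config(),
                            out_dir = NULL, seed = 1L) {
  if (is.null(simulate) == is.null(layers))
    stop("exactly one of 'simulate' or 'layers' must be given")
  if (!(tau_unstable > 0 || tau_unstable == 0) || tau_unstable >= tau_stable)
    stop("thresholds must satisfy 0 <= tau_unstable < tau_stable")
  if (!inherits(metric, "metric_config")) metric <- do.call(metric_config, metric)
  if (!inherits(ranking, "ranking_config")) ranking <- do.call(ranking_config, ranking)
  structure(list(simulate = simulate, layers = layers,
                 tau_unstable = tau_unstable, tau_stable = tau_stable,
                 metric = metric, ranking = ranking,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys: `seed`, `out_dir`, `tau_unstable`, `tau_stable`,
#' `simulate` (mapping of [world_params()] arguments), `layers` (mapping of
#' the four layer paths), `metric` (mapping of [metric_config()] arguments)
#' and `ranking` (mapping of [ranking_config()] arguments).
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("simulate", "layers", "tau_unstable", "tau_stable", "out_dir", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$metric)) args$metric <- y$metric
  if (!is.null(y$ranking)) args$ranking <- y$ranking
  do.call(pipeline_config, args)
}

#' Run the full screening pipeline
#'
#' simulate/load -> stability screen -> overlay derivation -> country
#' clipping -> per-country metrics -> limiting-factor ranking. All
#' randomness flows from `config$seed`; identical configuration and inputs
#' give identical outputs (byte-identical files when `out_dir` is set).
#'
#' @param config a [pipeline_config()], or a path to its YAML file.
#' @return List with `screen` (classification tibble), `source` and
#'   `receptor` (derived layers), `patches` (patch tibble), `table` (ranked
#'   country summary), and `manifest` (configuration echo, seed and
#'   per-stage record counts, including countries excluded for lacking a
#'   role). When `out_dir` is set the derived layers, patches, table and
#'   manifest are also written there.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))

  if (!is.null(config$simulate)) {
    wp <- do.call(world_params, c(list(seed = config$seed), config$simulate))
    world <- generate_world(wp)
    ecoregions <- world$ecoregions; hotspots <- world$hotspots
    degradation <- world$degradation; countries <- world$countries
    metric <- world$metric
  } else {
    ecoregions <- read_layer(config$layers$ecoregions, "ecoregions")
    hotspots <- read_layer(config$layers$hotspots, "hotspots")
    degradation <- read_layer(config$layers$degradation, "degradation")
    countries <- read_layer(config$layers$countries, "countries")
    metric <- config$metric
    world <- NULL
  }

  scr <- screen_ecoregions(ecoregions, config$tau_unstable, config$tau_stable)
  src <- derive_source(scr$unstable, hotspots)
  rec <- derive_receptor(scr$stable, degradation)
  patches <- rbind(clip_to_countries(src, countries, metric),
                   clip_to_countries(rec, countries, metric))
  table <- rank_countries(patches, countries, metric, config$ranking)

  manifest <- list(
    seed = config$seed,
    mode = metric$mode,
    tau_unstable = config$tau_unstable, tau_stable = config$tau_stable,
    area_threshold_km2 = config$ranking$area_threshold_km2,
    dist_threshold_km = config$ranking$dist_threshold_km,
    counts = list(
      ecoregions = nrow(ecoregions),
      unstable = sum(scr$classification$klass == "unstable"),
      stable = sum(scr$classification$klass == "stable"),
      hotspots = nrow(hotspots),
      degradation = nrow(degradation),
      countries = nrow(countries),
      source_patches = sum(patches$role == "source"),
      receptor_patches = sum(patches$role == "receptor"),
      ranked_countries = nrow(table)),
    excluded_countries = attr(table, "excluded"))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_derived_geojson(src$geometry, file.path(config$out_dir, "source.geojson"))
    write_derived_geojson(rec$geometry, file.path(config$out_dir, "receptor.geojson"))
    write_patches_geojson(patches, file.path(config$out_dir, "patches.geojson"))
    write_summary_table(table, file.path(config$out_dir, "table.csv"))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(world = world, screen = scr$classification, source = src, receptor = rec,
       patches = patches, table = table, manifest = manifest)
}

write_derived_geojson <- function(g, path) {
  feats <- if (geom_is_empty(g)) list() else
    list(list(type = "Feature", properties = list(),
              geometry = geojson_geometry(g)))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

write_patches_geojson <- function(patches, path) {
  feats <- lapply(seq_len(nrow(patches)), function(i)
    list(type = "Feature",
         properties = list(iso3 = patches$iso3[[i]], role = patches$role[[i]],
                           area_km2 = patches$area_km2[[i]]),
         geometry = geojson_geometry(patches$geometry[[i]])))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
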