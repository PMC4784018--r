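#' Ranking thresholds
#'
#' A country value is "limiting" when it fails its threshold: a source or
#' receptor area not greater than `area_threshold_km2` (default 15,000 km^2),
#' or a minimum source-receptor distance not less than `dist_threshold_km`
#' (default 500 km, the distance over which road transport of intact
#' soil/vegetation sods is still realistic within a day). Both comparisons
#' are strict, so a value sitting exactly at a threshold is limiting.
#'
#' @param area_threshold_km2 area threshold, km^2 (> 0).
#' @param dist_threshold_km distance threshold, km (> 0).
#' @return A list of class `ranking_config`.
#' @export
ranking_config <- function(area_threshold_km2 = 15000, dist_threshold_km = 500) {
  if (!is.numeric(area_threshold_km2) || area_threshold_km2 <= 0 ||
      !is.numeric(dist_threshold_km) || dist_threshold_km <= 0)
    stop("ranking thresholds must be positive")
  structure(list(area_threshold_km2 = area_threshold_km2,
                 dist_threshold_km = dist_threshold_km),
            class = "ranking_config")
}

est_categories <- c("best", "distance_limited", "receptor_limited",
                    "source_limited", "multiple_limited")

#' Limiting-factor flags and candidate category for countries
#'
#' Vectorised. A country with no limiting factor is `"best"`; exactly one
#' limiting factor gives `"distance_limited"`, `"receptor_limited"` or
#' `"source_limited"`; two or more give `"multiple_limited"`.
#'
#' @param source_area_km2,receptor_area_km2 total per-role areas, km^2.
#' @param min_dist_km minimum source-receptor distance, km.
#' @param config a [ranking_config()].
#' @return Tibble with logical columns `source_limiting`,
#'   `receptor_limiting`, `distance_limiting` and a `category` column.
#' @export
classify_country <- function(source_area_km2, receptor_area_km2, min_dist_km,
                             config = ranking_config()) {
  stopifnot(inherits(config, "ranking_config"))
  if (any(source_area_km2 < 0) || any(receptor_area_km2 < 0) || any(min_dist_km < 0))
    stop("areas and distances must be non-negative")
  sl <- source_area_km2 <= config$area_threshold_km2
  rl <- receptor_area_km2 <= config$area_threshold_km2
  dl <- min_dist_km >= config$dist_threshold_km
  nflag <- sl + rl + dl
  category <- ifelse(nflag == 0L, "best",
              ifelse(nflag >= 2L, "multiple_limited",
              ifelse(dl, "distance_limited",
              ifelse(rl, "receptor_limited", "source_limited"))))
  tibble::tibble(source_limiting = sl, receptor_limiting = rl,
                 distance_limiting = dl, category = category)
}

#' Summarise one country's patches
#'
#' Total per-role areas (reported in thousands of km^2) and the minimum
#' source-receptor distance for the patches of a single country.
#'
#' @param patches tibble of patches for one country ([clip_to_countries()]
#'   rows), containing at least one patch of each role.
#' @param config a [metric_config()].
#' @return List with `source_area_1e3km2`, `receptor_area_1e3km2`,
#'   `min_dist_km`.
#' @export
summarize_country <- function(patches, config = metric_config()) {
  stopifnot(is.data.frame(patches),
            all(c("role", "geometry", "area_km2") %in% names(patches)))
  if (length(unique(patches$iso3)) > 1L)
    stop("summarize_country() expects patches of a single country")
  src <- patches[patches$role == "source", ]
  rec <- patches[patches$role == "receptor", ]
  if (nrow(src) == 0L || nrow(rec) == 0L)
    stop("country lacks patches of one role; exclude it before summarising")
  list(source_area_1e3km2 = sum(src$area_km2) / 1000,
       receptor_area_1e3km2 = sum(rec$area_km2) / 1000,
       min_dist_km = min_patch_distance_km(src, rec, config))
}

#' Build and rank the per-country candidate table
#'
#' Assembles one row per country holding both source and receptor patches,
#' classifies limiting factors, and orders the table best-to-worst with a
#' deterministic composite key: category (best, then distance-, receptor-,
#' source-, multiple-limited), then source area descending, receptor area
#' descending, distance ascending, and country name as final alphabetical
#' tie-break. Countries missing a role are dropped and reported in the
#' `"excluded"` attribute.
#'
#' @param patches patch tibble from [clip_to_countries()] (both roles,
#'   possibly many countries, rbind-ed together).
#' @param countries country table (`iso3`, `name`) used for display names.
#' @param metric a [metric_config()].
#' @param config a [ranking_config()].
#' @return Ranked tibble with columns `iso3`, `name`,
#'   `source_area_1e3km2`, `receptor_area_1e3km2`, `min_dist_km`,
#'   `source_limiting`, `receptor_limiting`, `distance_limiting`,
#'   `category`, `rank`.
#' @export
rank_countries <- function(patches, countries, metric = metric_config(),
                           config = ranking_config()) {
  stopifnot(is.data.frame(patches))
  isos <- unique(patches$iso3)
  rows <- list(); excluded <- character(0)
  for (iso in isos) {
    p <- patches[patches$iso3 == iso, ]
    if (!all(c("source", "receptor") %in% p$role)) {
      excluded <- c(excluded, iso); next
    }
    s <- summarize_country(p, metric)
    nm <- countries$name[match(iso, countries$iso3)]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      iso3 = iso, name = if (is.na(nm)) iso else nm,
      source_area_1e3km2 = s$source_area_1e3km2,
      receptor_area_1e3km2 = s$receptor_area_1e3km2,
      min_dist_km = s$min_dist_km)
  }
  if (length(rows) == 0L) {
    out <- empty_summary_table()
  } else {
    out <- do.call(rbind, rows)
    cls <- classify_country(out$source_area_1e3km2 * 1000,
                            out$receptor_area_1e3km2 * 1000,
                            out$min_dist_km, config)
    out <- cbind(out, cls)
    out <- rank_table(out, config)
  }
  attr(out, "excluded") <- excluded
  out
}

#' Order classified summaries and assign ranks
#'
#' @param summaries tibble of classified country summaries (columns as in
#'   [rank_countries()] output, without `rank`).
#' @param config a [ranking_config()] (kept for interface symmetry; the
#'   ordering depends only on the already-assigned categories).
#' @return The same tibble, ordered, with a 1-based `rank` column.
#' @export
rank_table <- function(summaries, config = ranking_config()) {
  stopifnot(is.data.frame(summaries), "category" %in% names(summaries))
  if (!all(summaries$category %in% est_categories))
    stop("unknown category value")
  o <- order(match(summaries$category, est_categories),
             -summaries$source_area_1e3km2,
             -summaries$receptor_area_1e3km2,
             summaries$min_dist_km,
             summaries$name)
  out <- summaries[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  tibble::as_tibble(out)
}

empty_summary_table <- function() {
  tibble::tibble(iso3 = character(0), name = character(0),
                 source_area_1e3km2 = numeric(0),
                 receptor_area_1e3km2 = numeric(0),
                 min_dist_km = numeric(0),
                 source_limiting = logical(0), receptor_limiting = logical(0),
                 distance_limiting = logical(0),
                 category = character(0), rank = integer(0))
}

#' Published per-country reference summaries
#'
#' The 39-row per-country table from a published global screening for
#' ecosystem-scale translocation candidates: total source and receptor areas
#' (thousands of km^2), minimum source-receptor distance (km), and the
#' published limiting-factor marks. Useful as a worked example and as a
#' regression check for [classify_country()].
#'
#' @return Tibble with columns `country`, `source_area_1e3km2`,
#'   `receptor_area_1e3km2`, `min_dist_km`, `source_limiting`,
#'   `receptor_limiting`, `distance_limiting`.
#' @export
reference_country_summaries <- function() {
  path <- system.file("extdata", "country_reference_summaries.csv",
                      package = "estselect", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$source_limiting <- as.logical(df$source_limiting)
  df$receptor_limiting <- as.logical(df$receptor_limiting)
  df$distance_limiting <- as.logical(df$distance_limiting)
  tibble::as_tibble(df)
}
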