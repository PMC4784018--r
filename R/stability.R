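#' Mean climate stability across seven scenarios
#'
#' Ecoregions carry one climate-stability index per future-climate scenario,
#' each in \[0, 1\] (1 = complete overlap between current and projected
#' climate, 0 = none). The screening statistic is the equal-weight arithmetic
#' mean of the seven scenario indices.
#'
#' @param indices numeric vector of exactly 7 values in \[0, 1\].
#' @return The arithmetic mean, in \[0, 1\].
#' @export
mean_stability <- function(indices) {
  if (!is.numeric(indices) || length(indices) != 7L)
    stop("exactly 7 scenario indices are required, got ", length(indices))
  if (anyNA(indices) || any(indices < 0 | indices > 1))
    stop("stability indices must lie in [0, 1]")
  mean(indices)
}

#' Classify an ecoregion's mean stability index
#'
#' Strict thresholds: unstable below `tau_unstable`, stable above
#' `tau_stable`, intermediate otherwise — so the boundary values themselves
#' classify as intermediate.
#'
#' @param mean_index mean stability in \[0, 1\] (vectorised).
#' @param tau_unstable,tau_stable class thresholds (defaults 0.33 and 0.66).
#' @return Character vector: `"unstable"`, `"stable"` or `"intermediate"`.
#' @export
classify_stability <- function(mean_index, tau_unstable = 0.33, tau_stable = 0.66) {
  if (anyNA(mean_index) || any(mean_index < 0 | mean_index > 1))
    stop("mean_index must lie in [0, 1]")
  if (tau_unstable >= tau_stable) stop("tau_unstable must be < tau_stable")
  ifelse(mean_index < tau_unstable, "unstable",
         ifelse(mean_index > tau_stable, "stable", "intermediate"))
}

#' Screen ecoregions into unstable and stable layers
#'
#' Averages each ecoregion's seven scenario indices, classifies it, and
#' collects the geometries of each class into one multipolygon. Ecoregions
#' are treated as mutually interior-disjoint (they partition the land
#' surface), so the two outputs are interior-disjoint as well.
#'
#' @param ecoregions tibble with columns `id`, `geometry` (list of
#'   `est_geom`) and `stability` (list of length-7 numeric vectors), as
#'   returned by [read_layer()] or [generate_world()].
#' @param tau_unstable,tau_stable thresholds passed to [classify_stability()].
#' @return List with elements `unstable` and `stable` (`est_geom`) and
#'   `classification` (tibble: `ecoregion_id`, `mean_index`, `klass`).
#' @export
screen_ecoregions <- function(ecoregions, tau_unstable = 0.33, tau_stable = 0.66) {
  stopifnot(is.data.frame(ecoregions),
            all(c("id", "geometry", "stability") %in% names(ecoregions)))
  m <- vapply(ecoregions$stability, mean_stability, 0)
  klass <- classify_stability(m, tau_unstable, tau_stable)
  pick <- function(k) {
    sel <- which(klass == k)
    if (length(sel) == 0L) est_geom() else geom_combine(ecoregions$geometry[sel])
  }
  list(unstable = pick("unstable"),
       stable = pick("stable"),
       classification = tibble::tibble(ecoregion_id = ecoregions$id,
                                       mean_index = m, klass = klass))
}
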