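#' Rubric configuration
#'
#' The scoring rubric is driven by a configuration object holding the three
#' points tables (species, media, georeference), the positional-accuracy bin
#' edges and the band edges that map a summed total to a confidence level.
#'
#' @name rubric-config
NULL

# Enum token sets used across the package. These are the canonical spellings;
# readers can translate other dialects via aliases (see read_observations).
.clarity_levels    <- c("clear", "moderate", "poor", "unusable")
.features_levels   <- c("all", "most", "some", "none")
.visibility_levels <- c("easy_to_see", "visible_with_difficulty",
                        "requires_dissection_or_molecular")
.grade_levels      <- c("casual", "needs_id", "research_grade")
.accuracy_levels   <- c("incorrect", "uncertain", "correct")
.band_levels       <- c("unscorable", "low", "medium", "high")
.stop_reasons      <- c("molecular_required", "media_unusable",
                        "features_not_shown", "no_coordinates")

#' Default rubric configuration
#'
#' Point values satisfy the rubric's structural constraints: the attainable
#' totals span exactly 4 to 18, and the species and media steps carry a wider
#' point range than the georeference step because more factors bear on
#' confidence in the species and the media than on the georeference.
#'
#' Species points are assigned on diagnostic visibility crossed with whether
#' a very similar species occurs in the region; media points on image clarity
#' crossed with how many diagnostic features are shown; georeference points
#' by binning the positional accuracy radius (default bins: below 1 km,
#' 1 km to below 10 km, 10 km and above).
#'
#' @param strict_geo logical; if `TRUE`, a record with coordinates but no
#'   positional accuracy value is treated as a georeference stop instead of
#'   receiving the lowest georeference points.
#' @return A list of class `rubric_config` with elements `species_points`,
#'   `media_points`, `geo_points`, `geo_bin_edges_m`, `band_edges` and
#'   `strict_geo`.
#' @examples
#' cfg <- default_rubric_config()
#' cfg$band_edges$high
#' @export
default_rubric_config <- function(strict_geo = FALSE) {
  cfg <- list(
    species_points = list(
      easy_to_see             = c(no_similar = 7, similar = 5),
      visible_with_difficulty = c(no_similar = 3, similar = 1)
    ),
    media_points = list(
      clear    = c(all = 7, most = 5, some = 3),
      moderate = c(all = 5, most = 3, some = 3),
      poor     = c(all = 3, most = 1, some = 1)
    ),
    geo_points      = c(4, 3, 2),
    geo_bin_edges_m = c(1000, 10000),
    band_edges      = list(low = c(4L, 8L), medium = c(9L, 13L),
                           high = c(14L, 18L)),
    strict_geo      = isTRUE(strict_geo)
  )
  class(cfg) <- "rubric_config"
  validate_rubric_config(cfg)
}

#' Validate a rubric configuration
#'
#' Checks the structural invariants of the rubric: the minimum attainable
#' total equals the lower band edge and the maximum the upper one, the
#' species and media point ranges are wider than the georeference range,
#' bin edges are positive and increasing with one more georeference point
#' value than edges, and the band intervals are disjoint, contiguous and
#' cover the attainable totals.
#'
#' @param cfg a `rubric_config` list.
#' @return `cfg`, invisibly classed, if valid; otherwise a configuration
#'   error is raised.
#' @export
validate_rubric_config <- function(cfg) {
  need <- c("species_points", "media_points", "geo_points",
            "geo_bin_edges_m", "band_edges")
  miss <- setdiff(need, names(cfg))
  if (length(miss) > 0)
    stop_config("rubric config is missing element(s): %s",
                paste(miss, collapse = ", "))

  sp <- unlist(cfg$species_points)
  mp <- unlist(cfg$media_points)
  gp <- cfg$geo_points
  if (any(!is.finite(c(sp, mp, gp))) || any(c(sp, mp, gp) %% 1 != 0))
    stop_config("rubric points must be finite integers")

  edges <- cfg$geo_bin_edges_m
  if (length(gp) != length(edges) + 1L)
    stop_config("geo_points must have one more value than geo_bin_edges_m")
  if (any(edges <= 0) || is.unsorted(edges, strictly = TRUE))
    stop_config("geo_bin_edges_m must be positive and strictly increasing")

  bands <- cfg$band_edges
  if (!all(c("low", "medium", "high") %in% names(bands)))
    stop_config("band_edges must define low, medium and high intervals")
  lo <- vapply(bands, `[`, numeric(1), 1)[c("low", "medium", "high")]
  hi <- vapply(bands, `[`, numeric(1), 2)[c("low", "medium", "high")]
  if (any(hi < lo) || any(lo[-1] != hi[-3] + 1))
    stop_config("band intervals must be disjoint and contiguous")

  tot_min <- min(sp) + min(mp) + min(gp)
  tot_max <- max(sp) + max(mp) + max(gp)
  if (tot_min != lo[["low"]] || tot_max != hi[["high"]])
    stop_config(paste("attainable totals [%d, %d] do not match the band",
                      "range [%d, %d]"),
                tot_min, tot_max, lo[["low"]], hi[["high"]])

  rng <- function(x) max(x) - min(x)
  if (rng(sp) <= rng(gp) || rng(mp) <= rng(gp))
    stop_config(paste("species and media point ranges must be wider than",
                      "the georeference range"))

  class(cfg) <- "rubric_config"
  invisible(cfg)
}

#' Read a rubric configuration from YAML
#'
#' The YAML file holds the points tables keyed by enum-token strings, the
#' `geo_bin_edges_m` list, the `band_edges` list of two-element ranges and
#' optionally `strict_geo`. The configuration is validated on load.
#'
#' @param path path to a YAML file.
#' @return a validated `rubric_config`.
#' @export
read_rubric_config <- function(path) {
  if (!file.exists(path))
    stop_usage("rubric config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  cfg <- list(
    species_points = lapply(raw$species_points, function(x) unlist(x)),
    media_points   = lapply(raw$media_points, function(x) unlist(x)),
    geo_points     = as.numeric(unlist(raw$geo_points)),
    geo_bin_edges_m = as.numeric(unlist(raw$geo_bin_edges_m)),
    band_edges     = lapply(raw$band_edges, function(x) as.integer(unlist(x))),
    strict_geo     = isTRUE(raw$strict_geo)
  )
  cfg <- validate_rubric_config(cfg)
  cfg
}

#' Write a rubric configuration to YAML
#'
#' @param cfg a `rubric_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rubric_config <- function(cfg, path) {
  validate_rubric_config(cfg)
  out <- list(
    species_points = lapply(cfg$species_points, as.list),
    media_points   = lapply(cfg$media_points, as.list),
    geo_points     = as.list(cfg$geo_points),
    geo_bin_edges_m = as.list(cfg$geo_bin_edges_m),
    band_edges     = lapply(cfg$band_edges, as.list),
    strict_geo     = cfg$strict_geo
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
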