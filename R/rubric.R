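#' Three-step confidence rubric
#'
#' Confidence in a citizen-science observation is scored in three steps —
#' species, media, georeference — each of which can either award points or
#' hit a stop point that makes the observation unscorable. Step points are
#' summed to a total in 4..18 which is banded into low (4-8), medium (9-13)
#' or high (14-18) confidence.
#'
#' @name rubric
NULL

step_score <- function(step, points = NA_integer_, stop_reason = NA_character_) {
  structure(list(step = step, points = points, stop_reason = stop_reason),
            class = "step_score")
}

is_stop <- function(s) !is.na(s$stop_reason)

#' Score the species step
#'
#' Points depend on whether the species has one or more easy-to-see
#' diagnostic features and whether any very similar species occur in the
#' region. Species whose identification requires dissection or molecular
#' analysis hit a stop point.
#'
#' @param traits a single species' traits: a list or one-row data.frame with
#'   `diagnostic_visibility` (one of `easy_to_see`,
#'   `visible_with_difficulty`, `requires_dissection_or_molecular`) and
#'   logical `similar_species_in_region`.
#' @param config a [rubric_config][default_rubric_config].
#' @return a `step_score`: either points or a stop with reason
#'   `molecular_required`.
#' @export
score_species_step <- function(traits, config = default_rubric_config()) {
  vis <- as.character(traits$diagnostic_visibility)
  if (!vis %in% .visibility_levels)
    stop_data("unknown diagnostic_visibility token: %s", vis)
  if (vis == "requires_dissection_or_molecular")
    return(step_score("species", stop_reason = "molecular_required"))
  tab <- config$species_points[[vis]]
  if (is.null(tab))
    stop_config("species_points table has no row for visibility '%s'", vis)
  key <- if (isTRUE(as.logical(traits$similar_species_in_region)))
    "similar" else "no_similar"
  pts <- tab[[key]]
  if (is.null(pts) || is.na(pts))
    stop_config("species_points table has no entry for (%s, %s)", vis, key)
  step_score("species", points = as.integer(pts))
}

#' Score the media step
#'
#' Clear media showing all the diagnostic features needed for species-level
#' identification earn the most points. Media that are not clear enough to
#' support identification, or that show none of the required features, hit a
#' stop point.
#'
#' @param media a list or one-row data.frame with `clarity` (one of `clear`,
#'   `moderate`, `poor`, `unusable`) and `features_shown` (one of `all`,
#'   `most`, `some`, `none`).
#' @param config a [rubric_config][default_rubric_config].
#' @return a `step_score`: points, or a stop with reason `media_unusable` or
#'   `features_not_shown`.
#' @export
score_media_step <- function(media, config = default_rubric_config()) {
  clarity <- as.character(media$clarity)
  features <- as.character(media$features_shown)
  if (!clarity %in% .clarity_levels)
    stop_data("unknown media clarity token: %s", clarity)
  if (!features %in% .features_levels)
    stop_data("unknown features_shown token: %s", features)
  if (clarity == "unusable")
    return(step_score("media", stop_reason = "media_unusable"))
  if (features == "none")
    return(step_score("media", stop_reason = "features_not_shown"))
  tab <- config$media_points[[clarity]]
  if (is.null(tab))
    stop_config("media_points table has no row for clarity '%s'", clarity)
  pts <- tab[[features]]
  if (is.null(pts) || is.na(pts))
    stop_config("media_points table has no entry for (%s, %s)",
                clarity, features)
  step_score("media", points = as.integer(pts))
}

#' Score the georeference step
#'
#' Points are assigned by binning the positional accuracy radius: below 1 km
#' earns the highest georeference points under the default bins. An
#' observation without coordinates hits a stop point. A record with
#' coordinates but no stated accuracy radius receives the lowest
#' georeference points (degraded, not voided) unless the configuration sets
#' `strict_geo`, in which case it stops as if unreferenced.
#'
#' @param record a list or one-row data.frame with `latitude`, `longitude`
#'   and `positional_accuracy_m` (any of which may be `NA`).
#' @param config a [rubric_config][default_rubric_config].
#' @param warn_missing_accuracy emit a warning when accuracy is absent but
#'   coordinates are present (default `TRUE`).
#' @return a `step_score`: points, or a stop with reason `no_coordinates`.
#' @export
score_georeference_step <- function(record, config = default_rubric_config(),
                                    warn_missing_accuracy = TRUE) {
  lat <- suppressWarnings(as.numeric(record$latitude))
  lon <- suppressWarnings(as.numeric(record$longitude))
  if (is.na(lat) || is.na(lon))
    return(step_score("georeference", stop_reason = "no_coordinates"))
  acc <- suppressWarnings(as.numeric(record$positional_accuracy_m))
  if (is.na(acc)) {
    if (isTRUE(config$strict_geo))
      return(step_score("georeference", stop_reason = "no_coordinates"))
    if (warn_missing_accuracy)
      warning("positional accuracy absent with coordinates present; ",
              "assigning lowest georeference points", call. = FALSE)
    return(step_score("georeference",
                      points = as.integer(min(config$geo_points))))
  }
  if (acc < 0)
    stop_data("negative positional accuracy: %s", acc)
  bin <- findInterval(acc, config$geo_bin_edges_m) + 1L
  step_score("georeference", points = as.integer(config$geo_points[bin]))
}

#' Combine the three step scores
#'
#' If any step hit a stop point the observation is unscorable; the reported
#' stop reason is the first in step order (species, media, georeference).
#' Otherwise the points are summed and banded.
#'
#' @param species,media,geo `step_score`s from the three distinct steps.
#' @param config a [rubric_config][default_rubric_config].
#' @return a `confidence_result` list with elements `steps`, `total`
#'   (integer or `NA`), `band` (one of `low`, `medium`, `high`,
#'   `unscorable`) and `stop_reason`.
#' @export
combine_steps <- function(species, media, geo,
                          config = default_rubric_config()) {
  steps <- list(species, media, geo)
  kinds <- vapply(steps, `[[`, character(1), "step")
  if (!identical(sort(kinds), sort(c("species", "media", "georeference"))))
    stop_usage("combine_steps needs one score from each of the three steps, got: %s",
               paste(kinds, collapse = ", "))
  steps <- steps[match(c("species", "media", "georeference"), kinds)]
  stopped <- vapply(steps, is_stop, logical(1))
  if (any(stopped)) {
    reason <- steps[[which(stopped)[1]]]$stop_reason
    res <- list(steps = steps, total = NA_integer_, band = "unscorable",
                stop_reason = reason)
  } else {
    total <- sum(vapply(steps, `[[`, integer(1), "points"))
    res <- list(steps = steps, total = total,
                band = categorize_total(total, config),
                stop_reason = NA_character_)
  }
  class(res) <- "confidence_result"
  res
}

#' Band a summed rubric total
#'
#' @param total integer total of the three step points.
#' @param config a [rubric_config][default_rubric_config].
#' @return `"low"`, `"medium"` or `"high"`.
#' @export
categorize_total <- function(total, config = default_rubric_config()) {
  bands <- config$band_edges
  for (b in names(bands)) {
    if (total >= bands[[b]][1] && total <= bands[[b]][2]) return(b)
  }
  stop_config("total %s is outside the attainable range [%d, %d]; the points tables are misconfigured",
              total, bands$low[1], bands$high[2])
}

#' Score one observation against the rubric
#'
#' Composes the species, media and georeference steps for a single record,
#' looking the species' traits up in the registry.
#'
#' @param record a list or one-row data.frame with at least `species_name`,
#'   `media_clarity`, `media_features`, `latitude`, `longitude`,
#'   `positional_accuracy_m`.
#' @param registry a species-trait registry from [read_species_registry()]
#'   or built in code.
#' @param config a [rubric_config][default_rubric_config].
#' @param warn_missing_accuracy see [score_georeference_step()].
#' @return a `confidence_result`.
#' @export
score_observation <- function(record, registry,
                              config = default_rubric_config(),
                              warn_missing_accuracy = TRUE) {
  sp <- as.character(record$species_name)
  i <- match(sp, registry$species_name)
  if (is.na(i))
    stop_data("unregistered_species: %s", sp)
  if (is.na(record$media_clarity) || is.na(record$media_features))
    stop_data("missing media assessment for record %s",
              as.character(record$record_id))
  s <- score_species_step(registry[i, , drop = FALSE], config)
  m <- score_media_step(list(clarity = record$media_clarity,
                             features_shown = record$media_features), config)
  g <- score_georeference_step(record, config, warn_missing_accuracy)
  combine_steps(s, m, g, config)
}

#' Score every observation in a set
#'
#' Applies [score_observation()] to each record and appends the per-step
#' points, total, band and stop reason as columns. Warnings about absent
#' positional accuracy are collapsed into a single count reported once.
#'
#' @param obs an observation data.frame (see [read_observations()]).
#' @param registry a species-trait registry.
#' @param config a [rubric_config][default_rubric_config].
#' @return `obs` with columns `species_points`, `media_points`,
#'   `geo_points`, `total`, `band`, `stop_reason` appended; class
#'   `scored_obs`.
#' @examples
#' sim <- generate_dataset(generator_params(n = 20, seed = 1))
#' scored <- score_set(sim$observations, sim$registry)
#' table(scored$band)
#' @export
score_set <- function(obs, registry, config = default_rubric_config()) {
  n <- nrow(obs)
  sp_pts <- md_pts <- geo_pts <- total <- rep(NA_integer_, n)
  band <- character(n)
  reason <- rep(NA_character_, n)
  n_acc_missing <- 0L
  for (k in seq_len(n)) {
    rec <- obs[k, , drop = FALSE]
    if (!is.na(rec$latitude) && !is.na(rec$longitude) &&
        is.na(rec$positional_accuracy_m) && !isTRUE(config$strict_geo))
      n_acc_missing <- n_acc_missing + 1L
    res <- score_observation(rec, registry, config,
                             warn_missing_accuracy = FALSE)
    band[k] <- res$band
    reason[k] <- res$stop_reason
    if (!is.na(res$total)) {
      sp_pts[k]  <- res$steps[[1]]$points
      md_pts[k]  <- res$steps[[2]]$points
      geo_pts[k] <- res$steps[[3]]$points
      total[k]   <- res$total
    }
  }
  if (n_acc_missing > 0)
    warning(sprintf(paste("%d record(s) had coordinates but no positional",
                          "accuracy; lowest georeference points assigned"),
                    n_acc_missing), call. = FALSE)
  out <- cbind(obs,
               data.frame(species_points = sp_pts, media_points = md_pts,
                          geo_points = geo_pts, total = total, band = band,
                          stop_reason = reason, stringsAsFactors = FALSE))
  class(out) <- c("scored_obs", "data.frame")
  out
}

#' Enumerate all attainable rubric totals
#'
#' Crosses every non-stop level of the three steps under a configuration and
#' returns the resulting totals and bands — the full input lattice of the
#' rubric. Used to verify that totals span exactly the band range and that
#' every total belongs to exactly one band.
#'
#' @param config a [rubric_config][default_rubric_config].
#' @return a data.frame with one row per level combination: `visibility`,
#'   `similar`, `clarity`, `features`, `geo_bin`, the three step point
#'   values, `total` and `band`.
#' @export
enumerate_rubric <- function(config = default_rubric_config()) {
  sp <- expand.grid(visibility = names(config$species_points),
                    similar = c("no_similar", "similar"),
                    stringsAsFactors = FALSE)
  sp$sp_points <- mapply(function(v, s) config$species_points[[v]][[s]],
                         sp$visibility, sp$similar)
  md <- expand.grid(clarity = names(config$media_points),
                    features = names(config$media_points[[1]]),
                    stringsAsFactors = FALSE)
  md$md_points <- mapply(function(c, f) config$media_points[[c]][[f]],
                         md$clarity, md$features)
  geo <- data.frame(geo_bin = seq_along(config$geo_points),
                    geo_points = config$geo_points)
  grid <- merge(merge(sp, md, by = NULL), geo, by = NULL)
  grid$total <- grid$sp_points + grid$md_points + grid$geo_points
  grid$band <- vapply(grid$total, categorize_total, character(1),
                      config = config)
  grid
}
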