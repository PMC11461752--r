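#' Observation and registry I/O
#'
#' Readers and writers for observation tables in iNaturalist-export-style
#' CSV, the researcher-curated species-trait registry, and scored output.
#' Absent cells stay absent (`NA`) — they are never coerced to zero — and
#' rows violating record-level invariants are excluded and collected into a
#' rejection report rather than silently dropped.
#'
#' @name observation-io
NULL

.canonical_fields <- c("record_id", "species_name", "observed_on",
                       "latitude", "longitude", "positional_accuracy_m",
                       "media_clarity", "media_features", "quality_grade",
                       "accuracy_label")
.mandatory_fields <- c("record_id", "species_name", "quality_grade")

#' Column map for raw iNaturalist exports
#'
#' Maps the canonical field names used throughout the package to the column
#' names of a raw iNaturalist CSV export. Pass to [read_observations()] when
#' ingesting an unmodified export.
#'
#' @return a named character vector, names canonical and values as exported.
#' @export
inat_column_map <- function() {
  c(record_id = "id", species_name = "scientific_name",
    observed_on = "observed_on", latitude = "latitude",
    longitude = "longitude", positional_accuracy_m = "positional_accuracy",
    quality_grade = "quality_grade")
}

# iNaturalist spells the top grade "research"; canonical token is
# research_grade.
.default_grade_aliases <- c(research = "research_grade")

#' Read an observation table from CSV
#'
#' One `ObservationRecord` per data row. Blank coordinate or accuracy cells
#' become `NA` (never zero); rows with unparseable or out-of-range
#' coordinates, negative accuracy, or unknown enum tokens are excluded and
#' reported in the rejection report attached as `attr(x, "rejected")`.
#'
#' @param path CSV file with a header row.
#' @param column_map optional named character vector mapping canonical field
#'   names (`record_id`, `species_name`, `observed_on`, `latitude`,
#'   `longitude`, `positional_accuracy_m`, `media_clarity`,
#'   `media_features`, `quality_grade`, `accuracy_label`) to the file's
#'   column names; see [inat_column_map()] for the raw-export preset.
#' @param grade_aliases named character vector translating quality-grade
#'   spellings to canonical tokens (default maps `research` to
#'   `research_grade`).
#' @return a data.frame of class `obs_set` with the canonical columns,
#'   attributes `provenance` (the path) and `rejected` (a data.frame with
#'   `row`, `record_id`, `reason`).
#' @export
read_observations <- function(path, column_map = NULL,
                              grade_aliases = .default_grade_aliases) {
  if (!file.exists(path))
    stop_usage("observation file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = c("", "NA"))

  if (is.null(column_map))
    column_map <- stats::setNames(.canonical_fields, .canonical_fields)
  miss <- setdiff(.mandatory_fields,
                  names(column_map)[column_map %in% names(raw)])
  if (length(miss) > 0) {
    shown <- ifelse(miss %in% names(column_map), column_map[miss], miss)
    stop_data("missing mandatory column(s): %s", paste(shown, collapse = ", "))
  }

  n <- nrow(raw)
  out <- data.frame(matrix(NA_character_, nrow = n,
                           ncol = length(.canonical_fields),
                           dimnames = list(NULL, .canonical_fields)),
                    stringsAsFactors = FALSE)
  for (f in intersect(.canonical_fields, names(column_map))) {
    src <- column_map[[f]]
    if (src %in% names(raw)) out[[f]] <- raw[[src]]
  }

  # per-row validation; failures go to the rejection report
  reasons <- rep(NA_character_, n)
  flag <- function(i, why) {
    i <- i[is.na(reasons[i])]  # first failure wins
    reasons[i] <<- why
  }
  parse_num <- function(x) suppressWarnings(as.numeric(x))

  lat <- parse_num(out$latitude); lon <- parse_num(out$longitude)
  flag(which(!is.na(out$latitude) & is.na(lat)), "unparseable_latitude")
  flag(which(!is.na(out$longitude) & is.na(lon)), "unparseable_longitude")
  flag(which(!is.na(lat) & (lat < -90 | lat > 90)), "latitude_out_of_range")
  flag(which(!is.na(lon) & (lon < -180 | lon > 180)),
       "longitude_out_of_range")

  acc <- parse_num(out$positional_accuracy_m)
  flag(which(!is.na(out$positional_accuracy_m) & is.na(acc)),
       "unparseable_positional_accuracy")
  flag(which(!is.na(acc) & acc < 0), "negative_positional_accuracy")

  grade <- out$quality_grade
  hit <- grade %in% names(grade_aliases)
  grade[hit] <- grade_aliases[grade[hit]]
  flag(which(is.na(grade) | !grade %in% .grade_levels),
       "unknown_quality_grade")

  flag(which(!is.na(out$media_clarity) &
               !out$media_clarity %in% .clarity_levels),
       "unknown_media_clarity")
  flag(which(!is.na(out$media_features) &
               !out$media_features %in% .features_levels),
       "unknown_media_features")
  flag(which(!is.na(out$accuracy_label) &
               !out$accuracy_label %in% .accuracy_levels),
       "unknown_accuracy_label")

  out$latitude <- lat
  out$longitude <- lon
  out$positional_accuracy_m <- acc
  out$quality_grade <- grade

  bad <- !is.na(reasons)
  rejected <- data.frame(row = which(bad),
                         record_id = out$record_id[bad],
                         reason = reasons[bad], stringsAsFactors = FALSE)
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL

  dup <- unique(out$record_id[duplicated(out$record_id)])
  if (length(dup) > 0)
    stop_data("duplicate record_id value(s): %s", paste(dup, collapse = ", "))

  structure(out, class = c("obs_set", "data.frame"),
            provenance = path, rejected = rejected)
}

#' Read a species-trait registry from CSV
#'
#' The registry is a unique-key map from species name to the rubric's
#' species-step inputs: diagnostic visibility, presence of very similar
#' species in the region, and free-text notes.
#'
#' @param path CSV file with columns `species_name`,
#'   `diagnostic_visibility`, `similar_species_in_region` and optionally
#'   `notes`.
#' @return a data.frame of class `species_registry`.
#' @export
read_species_registry <- function(path) {
  if (!file.exists(path))
    stop_usage("registry file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = c("", "NA"))
  need <- c("species_name", "diagnostic_visibility",
            "similar_species_in_region")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0)
    stop_data("registry is missing column(s): %s", paste(miss, collapse = ", "))

  bad_vis <- which(!raw$diagnostic_visibility %in% .visibility_levels)
  if (length(bad_vis) > 0)
    stop_data("unknown diagnostic_visibility token '%s' in registry row %d",
              raw$diagnostic_visibility[bad_vis[1]], bad_vis[1])

  sim <- tolower(raw$similar_species_in_region)
  if (any(!sim %in% c("true", "false")))
    stop_data("similar_species_in_region must be true/false (registry row %d)",
              which(!sim %in% c("true", "false"))[1])

  dup <- unique(raw$species_name[duplicated(raw$species_name)])
  if (length(dup) > 0)
    stop_data("duplicate registry entries for: %s", paste(dup, collapse = ", "))

  out <- data.frame(species_name = raw$species_name,
                    diagnostic_visibility = raw$diagnostic_visibility,
                    similar_species_in_region = sim == "true",
                    notes = if ("notes" %in% names(raw)) raw$notes
                            else NA_character_,
                    stringsAsFactors = FALSE)
  structure(out, class = c("species_registry", "data.frame"))
}

#' Partition an observation set by georeference plausibility
#'
#' Applies a caller-supplied plausibility predicate to each record's
#' coordinates — e.g. marine species records falling on land are implausible
#' and excluded. Records without coordinates pass through unfiltered; they
#' hit the georeference stop point downstream instead.
#'
#' @param set an `obs_set` data.frame.
#' @param is_plausible `function(latitude, longitude)` returning `TRUE` for
#'   plausible positions. A predicate error on a record routes that record
#'   to the excluded set with reason `predicate_error`.
#' @return a list with `kept` and `excluded` (`excluded` carries an
#'   `exclusion_reason` column); together they partition the input.
#' @examples
#' sim <- generate_dataset(generator_params(n = 10, seed = 1))
#' mask <- make_rectangle_mask(-38, -30, 14, 34)
#' parts <- apply_habitat_plausibility_filter(sim$observations, mask)
#' nrow(parts$kept) + nrow(parts$excluded) == 10
#' @export
apply_habitat_plausibility_filter <- function(set, is_plausible) {
  n <- nrow(set)
  reason <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    lat <- set$latitude[k]; lon <- set$longitude[k]
    if (is.na(lat) || is.na(lon)) next
    ok <- tryCatch(isTRUE(is_plausible(lat, lon)), error = function(e) NA)
    if (is.na(ok)) reason[k] <- "predicate_error"
    else if (!ok) reason[k] <- "implausible_georeference"
  }
  drop <- !is.na(reason)
  excluded <- set[drop, , drop = FALSE]
  excluded$exclusion_reason <- reason[drop]
  kept <- set[!drop, , drop = FALSE]
  rownames(kept) <- rownames(excluded) <- NULL
  list(kept = kept, excluded = excluded)
}

#' Toy rectangular plausibility mask
#'
#' Returns a predicate accepting coordinates inside a latitude/longitude
#' rectangle. A stand-in for a real land/sea mask or polygon set, which the
#' caller supplies in production use.
#'
#' @param lat_min,lat_max,lon_min,lon_max rectangle bounds in decimal
#'   degrees.
#' @return `function(latitude, longitude)` returning a logical.
#' @export
make_rectangle_mask <- function(lat_min, lat_max, lon_min, lon_max) {
  force(lat_min); force(lat_max); force(lon_min); force(lon_max)
  function(latitude, longitude) {
    latitude >= lat_min && latitude <= lat_max &&
      longitude >= lon_min && longitude <= lon_max
  }
}

#' Write a scored observation set to CSV
#'
#' Output has all input columns plus the per-step points, total, band and
#' stop reason. Unscorable records get an empty total cell and a populated
#' `stop_reason`. Shared columns round-trip losslessly through
#' [read_observations()].
#'
#' @param set an `obs_set`, or a `scored_obs` from [score_set()] (in which
#'   case `results` is not needed).
#' @param path output CSV path.
#' @param results optional results data.frame (columns `species_points`,
#'   `media_points`, `geo_points`, `total`, `band`, `stop_reason`), one row
#'   per record of `set`.
#' @return `path`, invisibly.
#' @export
write_scored <- function(set, path, results = NULL) {
  if (is.null(results)) {
    if (!inherits(set, "scored_obs"))
      stop_usage("write_scored needs a scored set or an explicit results table")
    out <- set
  } else {
    if (nrow(results) != nrow(set))
      stop_data("results/record mismatch: %d results for %d records",
                nrow(results), nrow(set))
    out <- cbind(as.data.frame(set), results)
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write the rejection report of a read
#'
#' @param set an `obs_set` returned by [read_observations()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_rejection_report <- function(set, path) {
  rej <- attr(set, "rejected")
  if (is.null(rej))
    rej <- data.frame(row = integer(0), record_id = character(0),
                      reason = character(0))
  utils::write.csv(rej, path, row.names = FALSE, na = "")
  invisible(path)
}
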