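cfg <- default_rubric_config()

test_that("species step scores visibility crossed with lookalike presence, with the molecular stop", {
  top <- score_species_step(list(diagnostic_visibility = "easy_to_see",
                                 similar_species_in_region = FALSE), cfg)
  expect_equal(top$points, 7L)

  worst <- score_species_step(
    list(diagnostic_visibility = "visible_with_difficulty",
         similar_species_in_region = TRUE), cfg)
  expect_equal(worst$points, 1L)

  stop <- score_species_step(
    list(diagnostic_visibility = "requires_dissection_or_molecular",
         similar_species_in_region = FALSE), cfg)
  expect_equal(stop$stop_reason, "molecular_required")
  expect_true(is.na(stop$points))
})

test_that("media step scores clarity crossed with features shown, with both media stops", {
  expect_equal(score_media_step(list(clarity = "clear",
                                     features_shown = "all"), cfg)$points, 7L)
  expect_equal(score_media_step(list(clarity = "poor",
                                     features_shown = "some"), cfg)$points, 1L)
  expect_equal(score_media_step(list(clarity = "unusable",
                                     features_shown = "all"),
                                cfg)$stop_reason, "media_unusable")
  expect_equal(score_media_step(list(clarity = "clear",
                                     features_shown = "none"),
                                cfg)$stop_reason, "features_not_shown")
  # unusable clarity takes precedence over features when both stop
  expect_equal(score_media_step(list(clarity = "unusable",
                                     features_shown = "none"),
                                cfg)$stop_reason, "media_unusable")
})

test_that("georeference step bins accuracy half-open and stops without coordinates", {
  geo <- function(lat = -34, lon = 18, acc = NA)
    score_georeference_step(list(latitude = lat, longitude = lon,
                                 positional_accuracy_m = acc), cfg,
                            warn_missing_accuracy = FALSE)
  expect_equal(geo(acc = 500)$points, 4L)    # below 1 km: top points
  expect_equal(geo(acc = 999.9)$points, 4L)
  expect_equal(geo(acc = 1000)$points, 3L)   # lower-inclusive middle bin
  expect_equal(geo(acc = 9999)$points, 3L)
  expect_equal(geo(acc = 10000)$points, 2L)
  expect_equal(geo(lat = NA, lon = NA, acc = 5)$stop_reason,
               "no_coordinates")

  # accuracy absent with coordinates present degrades instead of stopping
  expect_equal(geo()$points, 2L)
  expect_warning(
    score_georeference_step(list(latitude = -34, longitude = 18,
                                 positional_accuracy_m = NA), cfg),
    "lowest georeference")
  strict <- default_rubric_config(strict_geo = TRUE)
  expect_equal(score_georeference_step(
    list(latitude = -34, longitude = 18, positional_accuracy_m = NA),
    strict)$stop_reason, "no_coordinates")
})

test_that("combine_steps sums points, bands the total and reports the first stop in step order", {
  s <- function(p) structure(list(step = "species", points = p,
                                  stop_reason = NA_character_),
                             class = "step_score")
  m <- function(p) structure(list(step = "media", points = p,
                                  stop_reason = NA_character_),
                             class = "step_score")
  g <- function(p) structure(list(step = "georeference", points = p,
                                  stop_reason = NA_character_),
                             class = "step_score")
  stop_step <- function(kind, why)
    structure(list(step = kind, points = NA_integer_, stop_reason = why),
              class = "step_score")

  hi <- combine_steps(s(7L), m(7L), g(4L), cfg)
  expect_equal(hi$total, 18L); expect_equal(hi$band, "high")
  lo <- combine_steps(s(1L), m(1L), g(2L), cfg)
  expect_equal(lo$total, 4L); expect_equal(lo$band, "low")

  one_stop <- combine_steps(stop_step("species", "molecular_required"),
                            m(7L), g(4L), cfg)
  expect_equal(one_stop$band, "unscorable")
  expect_equal(one_stop$stop_reason, "molecular_required")
  expect_true(is.na(one_stop$total))

  # multiple stops: species-step reason wins (step order)
  two_stops <- combine_steps(stop_step("species", "molecular_required"),
                             stop_step("media", "media_unusable"), g(4L),
                             cfg)
  expect_equal(two_stops$stop_reason, "molecular_required")

  expect_error(combine_steps(s(7L), s(5L), g(4L), cfg),
               class = "obsconf_usage_error")
})

test_that("categorize_total follows the published band edges and rejects out-of-range totals", {
  expect_equal(categorize_total(4, cfg), "low")
  expect_equal(categorize_total(8, cfg), "low")
  expect_equal(categorize_total(9, cfg), "medium")
  expect_equal(categorize_total(13, cfg), "medium")
  expect_equal(categorize_total(14, cfg), "high")
  expect_equal(categorize_total(18, cfg), "high")
  expect_error(categorize_total(19, cfg), class = "obsconf_config_error")
  expect_error(categorize_total(3, cfg), class = "obsconf_config_error")
})

test_that("score_observation composes the three steps through the registry", {
  reg <- test_registry()
  best <- score_observation(make_obs(), reg, cfg)
  expect_equal(best$total, 18L)
  expect_equal(best$band, "high")

  # a molecular-only species is unscorable whatever the media and geo
  mol <- score_observation(make_obs(species_name = "Ulva lactuca"), reg, cfg)
  expect_equal(mol$band, "unscorable")
  expect_equal(mol$stop_reason, "molecular_required")

  expect_error(score_observation(make_obs(species_name = "Nemo incognita"),
                                 reg, cfg),
               "unregistered_species", class = "obsconf_data_error")
})

test_that("full-lattice enumeration attains 4 to 18 with every total in exactly one band", {
  grid <- enumerate_rubric(cfg)
  expect_equal(min(grid$total), 4)
  expect_equal(max(grid$total), 18)
  for (t in unique(grid$total))
    expect_length(unique(grid$band[grid$total == t]), 1)
  # bands partition the attainable range
  expect_setequal(unique(grid$band), c("low", "medium", "high"))
  for (t in 4:18)
    expect_length(Filter(function(b) t >= cfg$band_edges[[b]][1] &&
                           t <= cfg$band_edges[[b]][2],
                         names(cfg$band_edges)), 1)
})

test_that("improving any single input never decreases the total or the band", {
  band_rank <- function(b) match(b, c("low", "medium", "high"))
  grid <- enumerate_rubric(cfg)
  vis_rank <- c(visible_with_difficulty = 1, easy_to_see = 2)
  sim_rank <- c(similar = 1, no_similar = 2)
  clar_rank <- c(poor = 1, moderate = 2, clear = 3)
  feat_rank <- c(some = 1, most = 2, all = 3)

  ranks <- data.frame(
    visibility = vis_rank[grid$visibility],
    similar = sim_rank[grid$similar],
    clarity = clar_rank[grid$clarity],
    features = feat_rank[grid$features],
    geo_bin = max(grid$geo_bin) + 1 - grid$geo_bin)  # smaller radius better

  checked <- 0L
  for (dim in names(ranks)) {
    others <- setdiff(names(ranks), dim)
    key <- do.call(paste, c(ranks[others], sep = "/"))
    for (i in seq_len(nrow(grid))) {
      j <- which(key == key[i] & ranks[[dim]] == ranks[[dim]][i] + 1)
      if (length(j) == 0) next
      checked <- checked + length(j)
      expect_true(all(grid$total[j] >= grid$total[i]),
                  info = sprintf("%s improvement at lattice row %d", dim, i))
      expect_true(all(band_rank(grid$band[j]) >= band_rank(grid$band[i])))
    }
  }
  expect_gt(checked, 100)  # the lattice walk actually covered edges
})

test_that("any stop condition dominates: unscorable regardless of the other steps", {
  reg <- test_registry()
  medias <- expand.grid(clarity = c("clear", "moderate", "poor", "unusable"),
                        features = c("all", "most", "some", "none"),
                        stringsAsFactors = FALSE)
  accs <- c(50, 5000, 50000, NA)

  # molecular species: every media/geo combination is unscorable
  for (i in seq_len(nrow(medias))) {
    for (acc in accs) {
      r <- score_observation(
        make_obs(species_name = "Ulva lactuca",
                 media_clarity = medias$clarity[i],
                 media_features = medias$features[i],
                 positional_accuracy_m = acc),
        reg, cfg, warn_missing_accuracy = FALSE)
      expect_equal(r$band, "unscorable")
    }
  }
  # media stops and the coordinate stop dominate likewise
  for (sp in c("Carcinus maenas", "Obelia dichotoma")) {
    r <- score_observation(make_obs(species_name = sp,
                                    media_clarity = "unusable"), reg, cfg)
    expect_equal(r$band, "unscorable")
    r <- score_observation(make_obs(species_name = sp,
                                    media_features = "none"), reg, cfg)
    expect_equal(r$band, "unscorable")
    r <- score_observation(make_obs(species_name = sp, latitude = NA,
                                    longitude = NA), reg, cfg)
    expect_equal(r$band, "unscorable")
    expect_equal(r$stop_reason, "no_coordinates")
  }
})

test_that("config validation rejects tables that break the structural constraints", {
  # attainable totals leaving the band range
  bad <- cfg
  bad$species_points$easy_to_see["no_similar"] <- 9
  expect_error(validate_rubric_config(bad), class = "obsconf_config_error")

  # georeference range as wide as the species range
  bad <- cfg
  bad$geo_points <- c(8, 3, 2)
  expect_error(validate_rubric_config(bad), class = "obsconf_config_error")

  # non-contiguous bands
  bad <- cfg
  bad$band_edges$medium <- c(10L, 13L)
  expect_error(validate_rubric_config(bad), class = "obsconf_config_error")

  # unsorted bin edges
  bad <- cfg
  bad$geo_bin_edges_m <- c(10000, 1000)
  expect_error(validate_rubric_config(bad), class = "obsconf_config_error")
})

test_that("rubric config round-trips through YAML with validation on load", {
  path <- tempfile(fileext = ".yml")
  write_rubric_config(cfg, path)
  back <- read_rubric_config(path)
  expect_equal(back$species_points, cfg$species_points)
  expect_equal(back$media_points, cfg$media_points)
  expect_equal(back$geo_points, cfg$geo_points)
  expect_equal(back$band_edges, cfg$band_edges)

  # corrupt the file: load must fail validation
  raw <- yaml::read_yaml(path)
  raw$geo_points <- list(9, 3, 2)
  yaml::write_yaml(raw, path)
  expect_error(read_rubric_config(path), class = "obsconf_config_error")
})
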