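# shared fixtures and independent oracles

# all-pairs brute-force Kendall tau-b: the oracle stays independent of the
# table-based implementation it checks
tau_oracle <- function(x, y) {
  n <- length(x)
  C <- D <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i])
      dy <- sign(y[j] - y[i])
      if (dx == 0) tx <- tx + 1
      if (dy == 0) ty <- ty + 1
      s <- dx * dy
      if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
    }
  }
  n0 <- n * (n - 1) / 2
  list(tau = (C - D) / sqrt((n0 - tx) * (n0 - ty)), C = C, D = D)
}

# a minimal valid observation row; override fields as needed
make_obs <- function(..., n = 1) {
  base <- data.frame(
    record_id = sprintf("r%03d", seq_len(n)),
    species_name = "Carcinus maenas",
    observed_on = "2022-01-01",
    latitude = -34.1, longitude = 18.4,
    positional_accuracy_m = 500,
    media_clarity = "clear", media_features = "all",
    quality_grade = "research_grade",
    accuracy_label = "correct",
    stringsAsFactors = FALSE)
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}

test_registry <- function() {
  data.frame(
    species_name = c("Carcinus maenas", "Ciona robusta",
                     "Obelia dichotoma", "Suberites ficus",
                     "Ulva lactuca"),
    diagnostic_visibility = c("easy_to_see", "easy_to_see",
                              "visible_with_difficulty",
                              "visible_with_difficulty",
                              "requires_dissection_or_molecular"),
    similar_species_in_region = c(FALSE, TRUE, TRUE, FALSE, FALSE),
    notes = NA_character_,
    stringsAsFactors = FALSE)
}

write_temp_csv <- function(df, dir = tempdir()) {
  path <- tempfile("obsconf-", tmpdir = dir, fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}
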