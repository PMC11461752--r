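#' Validation statistics
#'
#' Ordinal association between confidence, expert-assessed accuracy and the
#' platform quality grade is measured with Kendall's rank correlation in its
#' tie-corrected form (tau-b), the appropriate variant for heavily tied
#' ordinal data. Concordant/discordant pair counts and the tie-correction
#' terms are exposed alongside tau. Association strength is interpreted on
#' the conventional bands of Schober et al.'s correlation guide.
#'
#' @name validation-stats
NULL

#' Ordinal codings for the validation variables
#'
#' Defines the rank order of each ordinal variable. By default unscorable
#' observations are included as the lowest confidence rank; set
#' `include_unscorable = FALSE` to drop them pairwise instead.
#'
#' @param confidence_order,accuracy_order,grade_order character vectors
#'   giving each variable's levels from lowest to highest rank.
#' @param include_unscorable logical; include unscorable as the lowest
#'   confidence level (default `TRUE`).
#' @return a list of class `ordinal_coding`.
#' @export
ordinal_coding <- function(confidence_order = c("unscorable", "low",
                                                "medium", "high"),
                           accuracy_order = c("incorrect", "uncertain",
                                              "correct"),
                           grade_order = c("casual", "needs_id",
                                           "research_grade"),
                           include_unscorable = TRUE) {
  for (ord in list(confidence_order, accuracy_order, grade_order))
    if (anyDuplicated(ord))
      stop_config("ordinal orders must be duplicate-free")
  structure(list(confidence_order = confidence_order,
                 accuracy_order = accuracy_order,
                 grade_order = grade_order,
                 include_unscorable = isTRUE(include_unscorable)),
            class = "ordinal_coding")
}

#' Kendall's tau-b with tie corrections
#'
#' Counts concordant (C) and discordant (D) pairs over all unordered pairs
#' and computes `tau = (C - D) / sqrt((n0 - n1)(n0 - n2))` where
#' `n0 = n(n-1)/2` and `n1`, `n2` are the within-tie pair counts of `x` and
#' `y`. The two-sided p-value uses the normal approximation
#' `z = 3(C - D) / sqrt(n(n-1)(2n+5)/2)`.
#'
#' @param x,y equal-length sequences of ordinal values (numeric, integer or
#'   factor with ordered levels). Fully observed: `NA` is not accepted.
#' @return a list of class `tau_result`: `tau`, `n`, `concordant`,
#'   `discordant`, `n1`, `n2`, `p_value`, `strength`.
#' @examples
#' kendall_tau_b(c(1, 2, 3), c(1, 2, 3))$tau  # 1
#' @export
kendall_tau_b <- function(x, y) {
  if (is.factor(x)) x <- as.integer(x)
  if (is.factor(y)) y <- as.integer(y)
  if (!is.numeric(x) || !is.numeric(y))
    stop_usage("kendall_tau_b needs numeric or factor sequences")
  n <- length(x)
  if (length(y) != n)
    stop_usage("sequences differ in length: %d vs %d", n, length(y))
  if (n < 2)
    stop_data("kendall_tau_b needs at least 2 observations")
  if (anyNA(x) || anyNA(y))
    stop_data("kendall_tau_b requires fully observed sequences")

  # pair counts from the contingency table of distinct values
  N <- table(factor(x, levels = sort(unique(x))),
             factor(y, levels = sort(unique(y))))
  r <- nrow(N); c <- ncol(N)
  C <- 0; D <- 0
  for (i in seq_len(r)) {
    for (j in seq_len(c)) {
      nij <- N[i, j]
      if (nij == 0) next
      if (i < r) {
        below <- N[(i + 1):r, , drop = FALSE]
        if (j < c) C <- C + nij * sum(below[, (j + 1):c])
        if (j > 1) D <- D + nij * sum(below[, 1:(j - 1)])
      }
    }
  }

  n0 <- n * (n - 1) / 2
  tie_pairs <- function(tot) sum(tot * (tot - 1) / 2)
  n1 <- tie_pairs(rowSums(N))
  n2 <- tie_pairs(colSums(N))
  if (n0 - n1 <= 0 || n0 - n2 <= 0)
    stop_data("tau undefined: zero variance in one of the sequences")
  tau <- (C - D) / sqrt((n0 - n1) * (n0 - n2))

  res <- structure(list(tau = tau, n = n, concordant = C, discordant = D,
                        n1 = n1, n2 = n2, p_value = NA_real_,
                        strength = interpret_strength(tau)),
                   class = "tau_result")
  res$p_value <- tau_p_value(res)
  res
}

#' Two-sided p-value for a tau result
#'
#' Normal approximation based on the pair-count difference:
#' `z = 3(C - D) / sqrt(n(n-1)(2n+5)/2)`, `p = 2 * P(Z > |z|)`. Adequate at
#' the sample sizes this package targets (hundreds to thousands of
#' records).
#'
#' @param result a `tau_result` (or any list with `concordant`,
#'   `discordant`, `n`).
#' @return the two-sided p-value.
#' @export
tau_p_value <- function(result) {
  n <- result$n
  if (is.null(n) || n < 2)
    stop_data("p-value needs n >= 2")
  z <- 3 * (result$concordant - result$discordant) /
    sqrt(n * (n - 1) * (2 * n + 5) / 2)
  2 * stats::pnorm(-abs(z))
}

#' Interpret the strength of a rank correlation
#'
#' Conventional absolute-value bands: below 0.10 negligible, 0.10-0.40
#' weak, 0.40-0.70 moderate, 0.70-0.90 strong, 0.90 and above very strong
#' (lower bound inclusive).
#'
#' @param tau a correlation coefficient in `[-1, 1]`.
#' @return one of `"negligible"`, `"weak"`, `"moderate"`, `"strong"`,
#'   `"very_strong"`.
#' @export
interpret_strength <- function(tau) {
  a <- abs(tau)
  if (is.na(a) || a > 1)
    stop_data("|tau| must be at most 1, got %s", tau)
  if (a < 0.10) "negligible"
  else if (a < 0.40) "weak"
  else if (a < 0.70) "moderate"
  else if (a < 0.90) "strong"
  else "very_strong"
}

# map a validation variable name to its column and coded order
.ordinal_variable <- function(set, var, coding) {
  spec <- switch(var,
    confidence = list(col = "band", order = coding$confidence_order),
    accuracy = list(col = "accuracy_label", order = coding$accuracy_order),
    quality_grade = list(col = "quality_grade",
                         order = coding$grade_order),
    stop_usage("unknown variable '%s' (expected confidence, accuracy or quality_grade)",
               var))
  if (!spec$col %in% names(set))
    stop_data("set has no '%s' column for variable '%s'", spec$col, var)
  vals <- as.character(set[[spec$col]])
  if (var == "confidence" && !coding$include_unscorable) {
    vals[vals == "unscorable"] <- NA_character_
    spec$order <- setdiff(spec$order, "unscorable")
  }
  bad <- !is.na(vals) & !vals %in% spec$order
  if (any(bad))
    stop_data("value(s) outside the ordinal coding for %s: %s", var,
              paste(unique(vals[bad]), collapse = ", "))
  list(codes = match(vals, spec$order), order = spec$order)
}

#' Rank correlation between two variables of a scored set
#'
#' Encodes both variables to integer ranks via the ordinal coding and
#' delegates to [kendall_tau_b()]. Records with either value missing (or
#' excluded by the coding, e.g. unscorable confidence when
#' `include_unscorable = FALSE`) are dropped pairwise; the dropped count is
#' reported in the result as `n_dropped`.
#'
#' @param set a scored observation set (see [score_set()]).
#' @param var_x,var_y `"confidence"`, `"accuracy"` or `"quality_grade"`.
#' @param coding an [ordinal_coding()].
#' @return a `tau_result` with an `n_dropped` element appended.
#' @export
correlate <- function(set, var_x, var_y, coding = ordinal_coding()) {
  vx <- .ordinal_variable(set, var_x, coding)
  vy <- .ordinal_variable(set, var_y, coding)
  keep <- !is.na(vx$codes) & !is.na(vy$codes)
  res <- kendall_tau_b(vx$codes[keep], vy$codes[keep])
  res$n_dropped <- sum(!keep)
  res
}

#' Cross-tabulate two ordinal variables of a scored set
#'
#' @param set a scored observation set.
#' @param row,col variable names as in [correlate()].
#' @param coding an [ordinal_coding()].
#' @return a `contingency_table`: an integer matrix with ordered row and
#'   column labels and attributes `row_var`, `col_var`, `n_dropped`.
#' @export
crosstab <- function(set, row, col, coding = ordinal_coding()) {
  if (nrow(set) == 0)
    stop_data("empty_input: no records to cross-tabulate")
  vr <- .ordinal_variable(set, row, coding)
  vc <- .ordinal_variable(set, col, coding)
  keep <- !is.na(vr$codes) & !is.na(vc$codes)
  tab <- table(factor(vr$order[vr$codes[keep]], levels = vr$order),
               factor(vc$order[vc$codes[keep]], levels = vc$order))
  out <- unclass(as.matrix(tab))
  names(dimnames(out)) <- c(row, col)
  structure(out, class = c("contingency_table", class(out)),
            row_var = row, col_var = col, n_dropped = sum(!keep))
}

#' Marginal summary of a scored set
#'
#' Counts and percentages per confidence band, accuracy class and quality
#' grade, plus the retained fraction: the percentage of observations at or
#' above the retention threshold band (default medium — the
#' keep-medium-and-high retention rule). Percentages are rounded half-up to
#' one decimal at formatting; unrounded values are kept in the `raw_pct`
#' column.
#'
#' @param set a scored observation set (band column required; accuracy and
#'   grade tables are included when those columns carry data).
#' @param retention_threshold `"low"`, `"medium"` or `"high"`.
#' @return a list of class `summary_report`: `total`, `confidence`,
#'   `accuracy`, `quality_grade` (data.frames with `level`, `count`, `pct`,
#'   `raw_pct`) and `retained_fraction`.
#' @export
summarize_proportions <- function(set, retention_threshold = "medium") {
  if (nrow(set) == 0)
    stop_data("empty_input: nothing to summarise")
  if (!"band" %in% names(set))
    stop_data("set is not scored: no band column")
  if (!retention_threshold %in% c("low", "medium", "high"))
    stop_usage("retention_threshold must be low, medium or high")
  total <- nrow(set)

  tally <- function(values, levels) {
    counts <- as.integer(table(factor(values, levels = levels)))
    raw <- counts / total * 100
    data.frame(level = levels, count = counts,
               pct = round_half_up(raw, 1), raw_pct = raw,
               stringsAsFactors = FALSE)
  }

  conf <- tally(set$band, c("high", "medium", "low", "unscorable"))
  acc <- grade <- NULL
  if ("accuracy_label" %in% names(set) && any(!is.na(set$accuracy_label)))
    acc <- tally(set$accuracy_label, c("correct", "incorrect", "uncertain"))
  if ("quality_grade" %in% names(set) && any(!is.na(set$quality_grade)))
    grade <- tally(set$quality_grade,
                   c("research_grade", "needs_id", "casual"))

  scorable_order <- c("low", "medium", "high")
  keep_bands <- scorable_order[match(retention_threshold, scorable_order):3]
  retained_raw <- sum(set$band %in% keep_bands) / total * 100

  structure(list(total = total, confidence = conf, accuracy = acc,
                 quality_grade = grade,
                 retained_fraction = round_half_up(retained_raw, 1),
                 retained_fraction_raw = retained_raw,
                 retention_threshold = retention_threshold),
            class = "summary_report")
}

#' @export
print.summary_report <- function(x, ...) {
  cat(sprintf("Scored observation set: %d records\n", x$total))
  show <- function(tab, what) {
    if (is.null(tab)) return(invisible())
    cat(sprintf("\n%s:\n", what))
    for (i in seq_len(nrow(tab)))
      cat(sprintf("  %-15s %5d  (%.1f%%)\n",
                  tab$level[i], tab$count[i], tab$pct[i]))
  }
  show(x$confidence, "Confidence band")
  show(x$accuracy, "Accuracy")
  show(x$quality_grade, "Quality grade")
  cat(sprintf("\nRetained at %s-or-better confidence: %.1f%%\n",
              x$retention_threshold, x$retained_fraction))
  invisible(x)
}

#' @export
print.tau_result <- function(x, ...) {
  cat(sprintf(
    "Kendall tau-b = %.3f (n = %d, C = %.0f, D = %.0f, p = %.3g): %s\n",
    x$tau, x$n, x$concordant, x$discordant, x$p_value, x$strength))
  invisible(x)
}

#' Serialise a tau result to a one-line CSV record
#'
#' @param result a `tau_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tau_csv <- function(result, path) {
  utils::write.csv(data.frame(tau = result$tau, n = result$n,
                              concordant = result$concordant,
                              discordant = result$discordant,
                              p_value = result$p_value,
                              strength = result$strength),
                   path, row.names = FALSE)
  invisible(path)
}

#' Serialise a contingency table to CSV
#'
#' @param tab a `contingency_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_contingency_csv <- function(tab, path) {
  df <- as.data.frame.matrix(unclass(tab))
  df <- cbind(stats::setNames(data.frame(rownames(df)), attr(tab, "row_var")),
              df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialise a summary report to CSV
#'
#' One row per (grouping, level) with count and half-up-rounded percentage,
#' plus a retained-fraction row.
#'
#' @param report a `summary_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(report, path) {
  rows <- list()
  for (g in c("confidence", "accuracy", "quality_grade")) {
    tab <- report[[g]]
    if (is.null(tab)) next
    rows[[g]] <- data.frame(grouping = g, level = tab$level,
                            count = tab$count, pct = tab$pct,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(grouping = "retained_fraction",
                               level = paste0(report$retention_threshold,
                                              "_or_better"),
                               count = NA_integer_,
                               pct = report$retained_fraction))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
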