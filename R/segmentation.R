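# ISAC stage 2: per-subgroup score tables and chi-square contrasts.

# Assign each record to a segment of `variable`: PNR excluded, categories
# below the floor folded per the schema merge map, categories still below the
# floor after merging dropped. Returns a character vector aligned with the
# records (NA = not in any segment) plus the kept segment levels as an attr.
segment_assignments <- function(dataset, variable, min_segment_n) {
  assert_schema_variable(dataset$schema, variable)
  x <- dataset$records[[variable]]
  x[x == PNR] <- NA_character_
  merge_into <- dataset$schema$variables[[variable]]$merge_into
  counts <- table(x)
  small <- names(counts)[counts < min_segment_n]
  to_merge <- intersect(small, names(merge_into))
  if (length(to_merge)) {
    x[x %in% to_merge] <- merge_into[x[x %in% to_merge]]
    counts <- table(x)
  }
  keep <- names(counts)[counts >= min_segment_n]
  x[!(x %in% keep)] <- NA_character_
  declared <- dataset$schema$variables[[variable]]$categories
  levels <- c(intersect(declared, keep), setdiff(keep, declared))
  if (length(levels) == 0L) {
    stop_bwsqol(
      paste0("no category of '", variable, "' reaches the segmentation floor (",
             min_segment_n, ")"),
      "bwsqol_empty_segmentation"
    )
  }
  structure(x, levels = levels)
}

subset_dataset <- function(dataset, idx) {
  out <- dataset
  out$records <- dataset$records[idx, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

#' Per-segment best-worst score tables
#'
#' Splits the cleaned dataset by the categories of one demographic variable
#' and computes a [bws_score_table()] per subgroup. Respondents who did not
#' answer the item ([PNR]) are excluded from segmentation (they remain in
#' descriptive tables). Categories below `min_segment_n` are folded into a
#' larger category when the schema declares a merge target (e.g. the sparse
#' youngest age band into the adjacent adult band), and dropped otherwise.
#'
#' @param dataset A cleaned [bws_dataset()].
#' @param variable A schema variable name.
#' @param min_segment_n Minimum subgroup size (default 10).
#' @return List of `segment_profile` objects, each with components
#'   `variable`, `category`, `n` and `scores`.
#' @export
segment_scores <- function(dataset, variable, min_segment_n = 10) {
  assert_cleaned(dataset)
  seg <- segment_assignments(dataset, variable, min_segment_n)
  lapply(attr(seg, "levels"), function(cat) {
    idx <- which(!is.na(seg) & seg == cat)
    structure(
      list(variable = variable, category = cat, n = length(idx),
           scores = bws_score_table(subset_dataset(dataset, idx))),
      class = "segment_profile"
    )
  })
}

#' @export
print.segment_profile <- function(x, ...) {
  cat("Segment: ", x$variable, " = ", x$category, " (n = ", x$n, ")\n", sep = "")
  print(x$scores)
  invisible(x)
}

#' Chi-square contrast of choice distributions across segments
#'
#' Tests independence between segment membership and the attribute chosen
#' (best pick by default) with Pearson's chi-square on the segment x
#' attribute contingency table, without continuity correction. Attributes
#' never chosen are dropped from the table (degrees of freedom adjust
#' accordingly); a flag reports when any expected cell falls below 5, the
#' usual validity caution for the chi-square approximation.
#'
#' @param dataset A cleaned [bws_dataset()].
#' @param variable A schema variable name.
#' @param min_segment_n Minimum subgroup size before testing (default 10);
#'   segments are formed as in [segment_scores()].
#' @param choice Which pick to contrast: `"best"` (default) or `"worst"`.
#' @return A `segment_comparison`: list with `variable`, `choice`,
#'   `contingency`, `statistic`, `df`, `p_value`, `low_expected_flag`.
#' @export
compare_segments <- function(dataset, variable, min_segment_n = 10,
                             choice = c("best", "worst")) {
  assert_cleaned(dataset)
  choice <- match.arg(choice)
  seg <- segment_assignments(dataset, variable, min_segment_n)
  idx <- which(!is.na(seg))
  picks <- dataset$records[[choice]][idx]
  tab <- table(
    segment = factor(seg[idx], levels = attr(seg, "levels")),
    attribute = factor(picks, levels = dataset$attributes$id)
  )
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop_bwsqol(
      paste0("contingency table for '", variable, "' is degenerate (",
             nrow(tab), " segment(s) x ", ncol(tab), " attribute(s))"),
      "bwsqol_domain_error"
    )
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(
    list(
      variable = variable,
      choice = choice,
      contingency = tab,
      statistic = unname(ht$statistic),
      df = unname(ht$parameter),
      p_value = unname(ht$p.value),
      low_expected_flag = any(ht$expected < 5)
    ),
    class = "segment_comparison"
  )
}

#' @export
print.segment_comparison <- function(x, ...) {
  cat("Segment contrast: ", x$variable, " vs ", x$choice, " choice\n", sep = "")
  cat(sprintf("Chi-square: %.3f, df = %d, p = %.4g %s\n",
              x$statistic, x$df, x$p_value, significance_label(x$p_value)))
  if (x$low_expected_flag) {
    cat("note: some expected cell counts < 5; chi-square approximation is rough\n")
  }
  print(x$contingency)
  invisible(x)
}

#' Significance label for a p-value
#'
#' Conventional reporting thresholds: `"**"` for p < 0.01, `"*"` for
#' p < 0.05, `"."` for p < 0.10, empty otherwise.
#'
#' @param p_value Numeric vector of p-values in \[0, 1\].
#' @return Character vector of labels.
#' @export
significance_label <- function(p_value) {
  if (any(p_value < 0 | p_value > 1, na.rm = TRUE)) {
    stop_bwsqol("p-values must lie in [0, 1]", "bwsqol_domain_error")
  }
  vapply(p_value, function(p) {
    if (is.na(p)) return("")
    if (p < 0.01) "**" else if (p < 0.05) "*" else if (p < 0.10) "." else ""
  }, character(1))
}
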