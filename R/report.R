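# Orchestration of the three ISAC stages plus file outputs. The analysis
# path draws no random numbers: rerunning on the same input is byte-identical.

#' Run the full ISAC analysis pipeline
#'
#' Cleans the input, then runs the three stages in report order --
#' identification (descriptive tables), best-worst scoring with the Friedman
#' test, segmentation (per-variable score tables and chi-square contrasts)
#' and characterization (personas) -- and writes all outputs under
#' `output_dir`:
#' `cleaning_report.json`, `table1.csv` (stacked descriptives),
#' `table2.csv` (score table), `segments/<variable>.csv`,
#' `comparisons.json`, `personas.json` and `report.md`.
#'
#' @param input Path to a delimited survey file or a [bws_dataset()].
#' @param output_dir Output directory (created if needed); `NULL` to skip
#'   writing files and just return results.
#' @param schema,attributes Used when `input` is a path; see
#'   [read_responses()].
#' @param variables Demographic variables to segment on (default: all schema
#'   variables).
#' @param min_segment_n Segmentation floor (default 10).
#' @param persona_rules List of [persona_rule()]s (default:
#'   [default_persona_rules()]).
#' @param descriptive_preset Denominator/rounding preset for
#'   [descriptive_report()].
#' @param p_adjust Multiple-testing correction across the segmentation
#'   contrasts: `"none"` (default, matching the single-variable reporting
#'   convention) or `"bonferroni"`.
#' @param delim Field delimiter when `input` is a path.
#'
#' @return Invisibly, a list with `dataset`, `cleaning_report`,
#'   `descriptives`, `scores`, `friedman`, `segments`, `comparisons`,
#'   `personas`.
#' @export
run_analysis <- function(input, output_dir = NULL,
                         schema = qol_schema(), attributes = qol_attributes(),
                         variables = NULL, min_segment_n = 10,
                         persona_rules = default_persona_rules(),
                         descriptive_preset = c("published", "uniform"),
                         p_adjust = c("none", "bonferroni"),
                         delim = ",") {
  descriptive_preset <- match.arg(descriptive_preset)
  p_adjust <- match.arg(p_adjust)
  dataset <- if (inherits(input, "bws_dataset")) {
    input
  } else {
    read_responses(input, schema = schema, attributes = attributes, delim = delim)
  }
  variables <- variables %||% schema_variables(dataset$schema)

  cleaned <- clean_responses(dataset)
  dataset <- cleaned$dataset

  descriptives <- descriptive_report(dataset, descriptive_preset)
  scores <- bws_score_table(dataset)
  friedman <- bws_friedman(dataset)

  segments <- list()
  comparisons <- list()
  for (v in variables) {
    segments[[v]] <- tryCatch(
      segment_scores(dataset, v, min_segment_n),
      bwsqol_empty_segmentation = function(e) e
    )
    comparisons[[v]] <- tryCatch(
      compare_segments(dataset, v, min_segment_n),
      bwsqol_error = function(e) e
    )
  }
  ok <- !vapply(comparisons, inherits, logical(1), "condition")
  if (p_adjust == "bonferroni" && any(ok)) {
    p_raw <- vapply(comparisons[ok], `[[`, numeric(1), "p_value")
    p_adj <- stats::p.adjust(p_raw, method = "bonferroni")
    for (i in which(ok)) comparisons[[i]]$p_adjusted <- unname(p_adj[names(comparisons)[i]])
  }

  personas <- persona_gallery(dataset, persona_rules)

  results <- list(
    dataset = dataset, cleaning_report = cleaned$report,
    descriptives = descriptives, scores = scores, friedman = friedman,
    segments = segments, comparisons = comparisons, personas = personas
  )
  if (!is.null(output_dir)) write_analysis_outputs(results, output_dir)
  invisible(results)
}

write_analysis_outputs <- function(results, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(output_dir, "segments"), showWarnings = FALSE)

  write_cleaning_report(results$cleaning_report, file.path(output_dir, "cleaning_report.json"))

  stacked <- do.call(rbind, lapply(results$descriptives, function(t) {
    if (nrow(t) == 0L) return(NULL)
    data.frame(
      Variable = attr(t, "variable"),
      Category = ifelse(t$category == PNR, "PNR or missing", t$category),
      Count = t$count,
      `%` = formatC(t$percent, format = "f", digits = attr(t, "digits")),
      check.names = FALSE, stringsAsFactors = FALSE
    )
  }))
  utils::write.csv(stacked, file.path(output_dir, "table1.csv"), row.names = FALSE)

  write_score_table(results$scores, file.path(output_dir, "table2.csv"))

  for (v in names(results$segments)) {
    profs <- results$segments[[v]]
    if (inherits(profs, "condition")) next
    per_var <- do.call(rbind, lapply(profs, function(p) {
      df <- as.data.frame(p$scores)
      cbind(Segment = p$category, n = p$n, df, stringsAsFactors = FALSE)
    }))
    utils::write.csv(per_var, file.path(output_dir, "segments", paste0(v, ".csv")),
                     row.names = FALSE)
  }

  comp_json <- lapply(results$comparisons, function(cmp) {
    if (inherits(cmp, "condition")) {
      return(list(error = conditionMessage(cmp)))
    }
    out <- list(
      statistic = cmp$statistic, df = cmp$df, p_value = cmp$p_value,
      significance = significance_label(cmp$p_value),
      low_expected_flag = cmp$low_expected_flag
    )
    if (!is.null(cmp$p_adjusted)) out$p_adjusted <- cmp$p_adjusted
    out
  })
  jsonlite::write_json(comp_json, file.path(output_dir, "comparisons.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  write_personas(results$personas, file.path(output_dir, "personas.json"))

  writeLines(render_report_md(results), file.path(output_dir, "report.md"))
  invisible(output_dir)
}

render_report_md <- function(results) {
  rep <- results$cleaning_report
  lines <- c(
    "# Quality-of-life best-worst scaling analysis",
    "",
    sprintf("Input: %s", results$dataset$provenance),
    sprintf("Valid responses: %d of %d (removed: %s)", rep$n_valid, rep$n_raw,
            paste(names(rep$removed_by_reason), unlist(rep$removed_by_reason),
                  sep = "=", collapse = ", ")),
    "",
    "## Identification",
    ""
  )
  for (t in results$descriptives) {
    if (nrow(t) == 0L) next
    df <- data.frame(
      Category = ifelse(t$category == PNR, "PNR or missing", t$category),
      Count = t$count,
      `%` = formatC(t$percent, format = "f", digits = attr(t, "digits")),
      check.names = FALSE, stringsAsFactors = FALSE
    )
    lines <- c(lines, paste0("### ", attr(t, "variable")), "", md_table(df), "")
  }
  sc <- results$scores
  score_df <- data.frame(
    Variables = sc$label, `Best Frequency` = sc$best, `Worst Frequency` = sc$worst,
    `B-W` = sc$bw, `Mean (B-W)` = formatC(sc$mean_bw, format = "f", digits = 3),
    `Normalized Relative Weights (%)` = formatC(sc$weight, format = "f", digits = 2),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  fr <- results$friedman
  lines <- c(lines,
    "### Best-worst scores", "", md_table(score_df), "",
    sprintf("Friedman test statistic: %.2f (df = %d, p = %.4g); n = %d.",
            unname(fr$statistic), unname(fr$parameter), fr$p.value, fr$n),
    "",
    "## Segmentation", ""
  )
  for (v in names(results$comparisons)) {
    cmp <- results$comparisons[[v]]
    if (inherits(cmp, "condition")) {
      lines <- c(lines, sprintf("- %s: not tested (%s)", v, conditionMessage(cmp)))
    } else {
      lines <- c(lines, sprintf(
        "- %s: Chi-square %.3f, df %d, p = %.4g %s%s", v, cmp$statistic, cmp$df,
        cmp$p_value, significance_label(cmp$p_value),
        if (cmp$low_expected_flag) " (low expected counts)" else ""
      ))
    }
  }
  lines <- c(lines, "", "## Characterization", "")
  for (p in results$personas$personas) {
    labels <- stats::setNames(p$scores$label, p$scores$attribute_id)
    lines <- c(lines,
      paste0("### ", p$name),
      "",
      sprintf("- Segment: %s (n = %d)",
              paste(vapply(names(p$selector), function(v) {
                paste0(v, ": ", paste(p$selector[[v]], collapse = "/"))
              }, character(1)), collapse = "; "), p$n),
      sprintf("- Top priority: %s; secondary: %s", labels[p$top_attribute],
              labels[p$secondary_attribute]),
      sprintf("- Lowest priorities: %s",
              paste(labels[p$low_priority_attributes], collapse = ", ")),
      ""
    )
  }
  if (nrow(results$personas$skipped)) {
    lines <- c(lines, "Skipped persona rules:", "")
    lines <- c(lines, sprintf("- %s: %s", results$personas$skipped$descriptor,
                              results$personas$skipped$reason), "")
  }
  lines
}

#' Run a simulation and write its artifacts
#'
#' Writes `dataset.csv` (the survey file dialect of [write_dataset()]),
#' `ground_truth.json` and `config.yaml` under `output_dir`, logging the seed
#' and config so runs are auditable and repeatable.
#'
#' @param config A `bws_sim_config`.
#' @param output_dir Output directory (created if needed).
#' @return Invisibly, the `bws_simulation`.
#' @export
run_simulation <- function(config, output_dir) {
  sim <- generate_bws_data(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  write_dataset(sim$dataset, file.path(output_dir, "dataset.csv"))
  write_ground_truth(sim, file.path(output_dir, "ground_truth.json"))
  yaml::write_yaml(
    list(
      n_respondents = config$n_respondents, seed = config$seed,
      incomplete_rate = config$incomplete_rate,
      contradictory_rate = config$contradictory_rate,
      base_utilities = as.list(stats::setNames(config$base_utilities,
                                               config$attributes$id)),
      segments = lapply(config$segments, function(s) {
        list(selector = s$selector, shift = s$shift)
      }),
      provenance = sim$dataset$provenance
    ),
    file.path(output_dir, "config.yaml")
  )
  invisible(sim)
}
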