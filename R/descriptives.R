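#' Descriptive table for one demographic variable
#'
#' First ISAC stage (identification): category counts and percentages for a
#' demographic variable. Two denominator conventions are supported because
#' published survey tables mix them: `all_rows` divides by every respondent
#' (non-response shown as a "PNR or missing" row), `nonmissing_only` divides
#' by respondents who answered the item and drops the PNR row.
#'
#' Percentages are rounded half-away-from-zero. `digits` exists because
#' survey reports round different variables to different precision; see
#' [descriptive_report()] for the preset that reproduces the published
#' convention.
#'
#' @param dataset A [bws_dataset()].
#' @param variable A schema variable name.
#' @param denominator_mode `"all_rows"` (default) or `"nonmissing_only"`.
#' @param digits Decimal places for the percentage column (default 2).
#'
#' @return A `descriptive_table`: data frame with columns `category`,
#'   `count`, `percent`; attributes `variable`, `denominator`,
#'   `denominator_mode`, `digits`.
#' @export
#' @examples
#' sim <- generate_bws_data(bws_sim_preset("survey", n = 100, seed = 1))
#' demographic_table(sim$dataset, "gender", "nonmissing_only")
demographic_table <- function(dataset, variable,
                              denominator_mode = c("all_rows", "nonmissing_only"),
                              digits = 2) {
  denominator_mode <- match.arg(denominator_mode)
  assert_schema_variable(dataset$schema, variable)
  x <- dataset$records[[variable]]
  tab <- table(x)
  declared <- dataset$schema$variables[[variable]]$categories
  observed <- names(tab)
  # schema order first, then unknown categories verbatim, PNR always last
  order_cats <- c(
    intersect(declared, observed),
    setdiff(observed, c(declared, PNR)),
    intersect(PNR, observed)
  )
  counts <- as.integer(tab[order_cats])
  if (denominator_mode == "nonmissing_only") {
    keep <- order_cats != PNR
    order_cats <- order_cats[keep]
    counts <- counts[keep]
  }
  denominator <- sum(counts)
  percent <- if (denominator > 0) {
    round_half_away(100 * counts / denominator, digits)
  } else {
    rep(NA_real_, length(counts))
  }
  out <- data.frame(
    category = order_cats, count = counts, percent = percent,
    stringsAsFactors = FALSE
  )
  structure(out,
    variable = variable, denominator = denominator,
    denominator_mode = denominator_mode, digits = digits,
    class = c("descriptive_table", "data.frame")
  )
}

#' @export
print.descriptive_table <- function(x, ...) {
  cat("Descriptive table: ", attr(x, "variable"),
      " (denominator ", attr(x, "denominator"), ", ",
      attr(x, "denominator_mode"), ")\n", sep = "")
  shown <- x
  shown$category[shown$category == PNR] <- "PNR or missing"
  shown$percent <- formatC(shown$percent, format = "f", digits = attr(x, "digits"))
  print.data.frame(shown, row.names = FALSE)
  invisible(x)
}

#' Descriptive tables for every schema variable
#'
#' Convenience wrapper producing one [demographic_table()] per variable.
#' The `"published"` preset reproduces the reporting convention of the source
#' survey: gender tabulated over respondents who answered (2 dp), age over
#' all respondents (2 dp), and the remaining variables over all respondents
#' at 1 dp. The `"uniform"` preset applies `all_rows` and 2 dp everywhere.
#'
#' @param dataset A [bws_dataset()].
#' @param preset `"published"` or `"uniform"`.
#' @return Named list of `descriptive_table` objects.
#' @export
descriptive_report <- function(dataset, preset = c("published", "uniform")) {
  preset <- match.arg(preset)
  vars <- schema_variables(dataset$schema)
  out <- lapply(vars, function(v) {
    if (preset == "published") {
      mode <- if (v == "gender") "nonmissing_only" else "all_rows"
      digits <- if (v %in% c("gender", "age_group")) 2 else 1
    } else {
      mode <- "all_rows"
      digits <- 2
    }
    demographic_table(dataset, v, mode, digits)
  })
  names(out) <- vars
  out
}

#' Serialize a descriptive table to CSV (with a JSON sidecar)
#'
#' Writes a three-column CSV (`Category`, `Count`, `%`) and, next to it, a
#' `<path>.json` sidecar recording the variable, denominator and
#' denominator mode.
#'
#' @param x A `descriptive_table`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_descriptive_table <- function(x, path) {
  out <- data.frame(
    Category = ifelse(x$category == PNR, "PNR or missing", x$category),
    Count = x$count,
    `%` = formatC(x$percent, format = "f", digits = attr(x, "digits")),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  jsonlite::write_json(
    list(
      variable = attr(x, "variable"),
      denominator = attr(x, "denominator"),
      denominator_mode = attr(x, "denominator_mode"),
      digits = attr(x, "digits")
    ),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Required sample size for estimating a proportion
#'
#' Normal-approximation sample size for estimating a population proportion
#' with a given confidence level and margin of error (half-width), for an
#' unbounded population:
#' \deqn{n = \lceil z^2 \, p(1-p) / e^2 \rceil}
#' where `z` is the standard-normal quantile of the confidence level. The
#' conservative default `p = 0.5` maximizes the requirement.
#'
#' @param margin Margin of error `e`, in (0, 1).
#' @param p Anticipated proportion, in (0, 1); default 0.5.
#' @param confidence Confidence level, in (0, 1); default 0.95.
#' @return Integer sample size.
#' @export
#' @examples
#' required_sample_size(margin = 0.06)  # 267
required_sample_size <- function(margin, p = 0.5, confidence = 0.95) {
  if (!is.numeric(margin) || length(margin) != 1L || margin <= 0 || margin >= 1) {
    stop_bwsqol("`margin` must be a single number in (0, 1)", "bwsqol_domain_error")
  }
  if (p <= 0 || p >= 1) stop_bwsqol("`p` must be in (0, 1)", "bwsqol_domain_error")
  if (confidence <= 0 || confidence >= 1) {
    stop_bwsqol("`confidence` must be in (0, 1)", "bwsqol_domain_error")
  }
  z <- stats::qnorm((1 + confidence) / 2)
  as.integer(ceiling(z^2 * p * (1 - p) / margin^2))
}

#' Margin of error achieved by a given sample size
#'
#' Inverse of [required_sample_size()]: the half-width of the
#' normal-approximation confidence interval for a proportion at sample size
#' `n`, \eqn{e = z \sqrt{p(1-p)/n}}.
#'
#' @param n Sample size (>= 1).
#' @param p Anticipated proportion; default 0.5 (worst case).
#' @param confidence Confidence level; default 0.95.
#' @return The margin of error as a proportion.
#' @export
#' @examples
#' achieved_margin(213)  # ~0.0671
achieved_margin <- function(n, p = 0.5, confidence = 0.95) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop_bwsqol("`n` must be a single count >= 1", "bwsqol_domain_error")
  }
  if (p <= 0 || p >= 1) stop_bwsqol("`p` must be in (0, 1)", "bwsqol_domain_error")
  z <- stats::qnorm((1 + confidence) / 2)
  z * sqrt(p * (1 - p) / n)
}
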