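#' Sentinel category for unanswered demographic items
#'
#' Demographic non-response is kept as a first-class reporting category
#' ("prefer not to respond or missing"), never treated as grounds for record
#' removal. Descriptive tables display it last; segment-level inference
#' excludes it.
#'
#' @format A length-one character constant, `"PNR"`.
#' @export
PNR <- "PNR"

#' Declare a demographic schema
#'
#' A schema names the demographic variables a survey collects, the category
#' order used in descriptive tables, and an optional merge map per variable
#' directing small categories into larger ones during segmentation (e.g.
#' folding a sparse youngest age band into the adjacent adult band).
#'
#' @param variables Named list; one element per variable. Each element is a
#'   list with components `categories` (character vector, display order) and
#'   optionally `merge_into` (named character vector mapping a category to the
#'   category that absorbs it when it falls below the segmentation floor).
#'
#' @return An object of class `demographic_schema`.
#' @seealso [qol_schema()] for the default six-variable schema.
#' @export
demographic_schema <- function(variables) {
  if (!is.list(variables) || is.null(names(variables)) || any(!nzchar(names(variables)))) {
    stop("`variables` must be a fully named list")
  }
  for (v in names(variables)) {
    spec <- variables[[v]]
    if (is.character(spec)) spec <- list(categories = spec)
    if (is.null(spec$categories) || !is.character(spec$categories)) {
      stop("variable '", v, "' must declare a character vector of categories")
    }
    if (anyDuplicated(spec$categories)) {
      stop("variable '", v, "' has duplicated categories")
    }
    spec$merge_into <- spec$merge_into %||% character(0)
    if (length(spec$merge_into)) {
      bad <- setdiff(c(names(spec$merge_into), spec$merge_into), spec$categories)
      if (length(bad)) {
        stop("merge map of '", v, "' references unknown categories: ",
             paste(bad, collapse = ", "))
      }
    }
    variables[[v]] <- spec
  }
  structure(list(variables = variables), class = "demographic_schema")
}

#' Default demographic schema of the quality-of-life survey
#'
#' Six variables -- gender, age group, race, education, relationship status
#' and employment status -- with the category sets of the source telephone
#' survey of low-income community residents. The age variable declares a
#' merge of the sparse youngest band ("Young Adults (18-24)") into
#' "Adults (25-54)" for segmentation.
#'
#' @return A [demographic_schema()].
#' @export
qol_schema <- function() {
  demographic_schema(list(
    gender = list(categories = c("Female", "Male")),
    age_group = list(
      categories = c("Young Adults (18-24)", "Adults (25-54)",
                     "Early Seniors (55-64)", "Seniors (65+)"),
      merge_into = c("Young Adults (18-24)" = "Adults (25-54)")
    ),
    race = list(categories = c("American Indian or Alaska Native",
                               "Black or African American", "White")),
    education = list(categories = c(
      "Master's degree or higher", "Bachelor's degree", "Associate's degree",
      "Some college but did not complete degree",
      "High school graduate or GED completed", "Some high school"
    )),
    relationship = list(categories = c(
      "Married and living with spouse", "Married and not living with spouse",
      "Single", "Committed relationship, not married", "Not sure"
    )),
    employment = list(categories = c(
      "Working full-time", "Working part-time", "Retired",
      "Stay-at-home parent", "Unemployed", "Disabled"
    ))
  ))
}

#' @export
print.demographic_schema <- function(x, ...) {
  cat("Demographic schema (", length(x$variables), " variables)\n", sep = "")
  for (v in names(x$variables)) {
    cat("  ", v, ": ", paste(x$variables[[v]]$categories, collapse = "; "), "\n", sep = "")
    mi <- x$variables[[v]]$merge_into
    if (length(mi)) {
      cat("    merge: ", paste(names(mi), "->", mi, collapse = "; "), "\n", sep = "")
    }
  }
  invisible(x)
}

schema_variables <- function(schema) names(schema$variables)

assert_schema_variable <- function(schema, variable) {
  if (!variable %in% schema_variables(schema)) {
    stop_bwsqol(
      paste0("variable '", variable, "' is not declared in the schema (",
             paste(schema_variables(schema), collapse = ", "), ")"),
      "bwsqol_schema_error"
    )
  }
  invisible(variable)
}
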