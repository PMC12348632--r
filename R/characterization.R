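# ISAC stage 3: deterministic persona construction from segment profiles.

#' Define a persona selection rule
#'
#' A persona rule selects the respondents a persona summarizes: a conjunction
#' of demographic conditions, each matching one variable against one or more
#' acceptable categories (so coarse groupings like "low education" can span
#' several categories).
#'
#' @param selector Named list: names are schema variables, values are
#'   character vectors of acceptable categories (a record matches when every
#'   variable's value is among them).
#' @param min_n Minimum number of matching respondents required before a
#'   persona is built (default 10).
#' @param descriptor Short demographic phrase used in the persona name
#'   (e.g. "Retired Female"); defaults to the selector values joined by
#'   spaces.
#'
#' @return A `persona_rule`.
#' @export
#' @examples
#' persona_rule(list(employment = "Retired", gender = "Female"),
#'              descriptor = "Retired Female")
persona_rule <- function(selector, min_n = 10, descriptor = NULL) {
  if (!is.list(selector) || length(selector) == 0L ||
      is.null(names(selector)) || any(!nzchar(names(selector)))) {
    stop_bwsqol("`selector` must be a non-empty named list", "bwsqol_domain_error")
  }
  if (anyDuplicated(names(selector))) {
    stop_bwsqol("selector variables must be distinct", "bwsqol_domain_error")
  }
  selector <- lapply(selector, as.character)
  if (any(vapply(selector, length, 1L) == 0L)) {
    stop_bwsqol("every selector condition needs at least one category",
                "bwsqol_domain_error")
  }
  descriptor <- descriptor %||%
    paste(vapply(selector, `[`, character(1), 1L), collapse = " ")
  structure(list(selector = selector, min_n = min_n, descriptor = descriptor),
            class = "persona_rule")
}

#' @export
print.persona_rule <- function(x, ...) {
  conds <- vapply(names(x$selector), function(v) {
    paste0(v, " in {", paste(x$selector[[v]], collapse = ", "), "}")
  }, character(1))
  cat("Persona rule '", x$descriptor, "': ", paste(conds, collapse = " & "),
      " (min n = ", x$min_n, ")\n", sep = "")
  invisible(x)
}

match_rule <- function(dataset, rule) {
  for (v in names(rule$selector)) assert_schema_variable(dataset$schema, v)
  idx <- rep(TRUE, nrow(dataset$records))
  for (v in names(rule$selector)) {
    idx <- idx & dataset$records[[v]] %in% rule$selector[[v]]
  }
  which(idx)
}

#' Build a persona from a segment of the data
#'
#' A persona is a structured archetype of the respondents matched by a
#' [persona_rule()]: its name combines the segment's top-priority attribute
#' with the rule's demographic descriptor, and it carries the top, secondary
#' and two lowest-priority attributes with the full score table. Construction
#' is a pure function of (dataset, rule): rerunning is byte-identical.
#'
#' @param dataset A cleaned [bws_dataset()].
#' @param rule A [persona_rule()].
#' @return A `bws_persona`: list with `name`, `descriptor`, `selector`, `n`,
#'   `top_attribute`, `secondary_attribute`, `low_priority_attributes`
#'   (bottom two, ascending B-W), `tie_flag` (TRUE when all B-W scores are
#'   equal so the top is decided purely by the tie-break), and `scores`.
#' @export
build_persona <- function(dataset, rule) {
  assert_cleaned(dataset)
  idx <- match_rule(dataset, rule)
  if (length(idx) < rule$min_n) {
    stop_bwsqol(
      paste0("persona rule '", rule$descriptor, "' matches only ", length(idx),
             " record(s); ", rule$min_n, " required"),
      "bwsqol_insufficient_support",
      n_matched = length(idx)
    )
  }
  scores <- bws_score_table(subset_dataset(dataset, idx))
  by_rank <- scores[order(scores$rank), ]
  J <- nrow(by_rank)
  top <- by_rank$attribute_id[1L]
  name <- trimws(paste(by_rank$label[1L], "Focused", rule$descriptor))
  structure(
    list(
      name = name,
      descriptor = rule$descriptor,
      selector = rule$selector,
      n = length(idx),
      top_attribute = top,
      secondary_attribute = by_rank$attribute_id[2L],
      low_priority_attributes = by_rank$attribute_id[c(J, J - 1L)],
      tie_flag = all(scores$bw == scores$bw[1L]),
      scores = scores
    ),
    class = "bws_persona"
  )
}

#' @export
print.bws_persona <- function(x, ...) {
  cat("Persona: ", x$name, " (n = ", x$n, ")\n", sep = "")
  cat("  top: ", x$top_attribute, "; secondary: ", x$secondary_attribute,
      "; low priority: ", paste(x$low_priority_attributes, collapse = ", "),
      "\n", sep = "")
  if (x$tie_flag) cat("  note: all B-W scores tied; top chosen by tie-break\n")
  invisible(x)
}

#' Build a gallery of personas
#'
#' Applies each rule in turn; rules without enough matching respondents are
#' skipped (not fatal) and reported alongside the gallery. Duplicated rules
#' yield duplicated personas -- construction is deterministic and performs no
#' deduplication.
#'
#' @param dataset A cleaned [bws_dataset()].
#' @param rules List of [persona_rule()] objects (default:
#'   [default_persona_rules()]).
#' @return A `persona_gallery`: list with `personas` (list of `bws_persona`)
#'   and `skipped` (data frame of descriptor + reason).
#' @export
persona_gallery <- function(dataset, rules = default_persona_rules()) {
  personas <- list()
  skipped <- data.frame(descriptor = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (rule in rules) {
    res <- tryCatch(build_persona(dataset, rule), bwsqol_insufficient_support = identity)
    if (inherits(res, "bws_persona")) {
      personas[[length(personas) + 1L]] <- res
    } else {
      skipped <- rbind(skipped, data.frame(
        descriptor = rule$descriptor, reason = conditionMessage(res),
        stringsAsFactors = FALSE
      ))
    }
  }
  structure(list(personas = personas, skipped = skipped),
            class = "persona_gallery")
}

#' @export
print.persona_gallery <- function(x, ...) {
  cat("Persona gallery: ", length(x$personas), " persona(s), ",
      nrow(x$skipped), " rule(s) skipped\n", sep = "")
  for (p in x$personas) print(p)
  if (nrow(x$skipped)) {
    cat("skipped:\n")
    print.data.frame(x$skipped, row.names = FALSE)
  }
  invisible(x)
}

#' Education groupings used by the default persona rules
#'
#' "Educated" covers bachelor's degrees and above; "low education" covers
#' some college or less, excluding associate's degrees which sit between the
#' two groups. Override by building [persona_rule()]s with explicit category
#' sets.
#'
#' @return Named list with components `educated` and `low_education`.
#' @export
education_groups <- function() {
  list(
    educated = c("Master's degree or higher", "Bachelor's degree"),
    low_education = c("Some college but did not complete degree",
                      "High school graduate or GED completed",
                      "Some high school")
  )
}

#' Default persona rules
#'
#' The four archetype selectors of the quality-of-life study: a retired
#' married female persona, a full-time working single male persona, a working
#' single female persona with lower education, and an unemployed single
#' persona with lower education.
#'
#' @param min_n Minimum support per rule (default 10).
#' @return List of four [persona_rule()] objects.
#' @export
default_persona_rules <- function(min_n = 10) {
  low_ed <- education_groups()$low_education
  list(
    persona_rule(
      list(employment = "Retired", relationship = "Married and living with spouse",
           gender = "Female"),
      min_n = min_n, descriptor = "Retired Female"
    ),
    persona_rule(
      list(employment = "Working full-time", relationship = "Single",
           gender = "Male"),
      min_n = min_n, descriptor = "Working Single Male"
    ),
    persona_rule(
      list(employment = "Working full-time", relationship = "Single",
           gender = "Female", education = low_ed),
      min_n = min_n, descriptor = "Working Single Female"
    ),
    persona_rule(
      list(employment = "Unemployed", relationship = "Single", education = low_ed),
      min_n = min_n, descriptor = "Unemployed Single"
    )
  )
}

persona_to_list <- function(p) {
  list(
    name = p$name,
    descriptor = p$descriptor,
    selector = p$selector,
    n = p$n,
    top_attribute = p$top_attribute,
    secondary_attribute = p$secondary_attribute,
    low_priority_attributes = p$low_priority_attributes,
    tie_flag = p$tie_flag,
    scores = as.data.frame(p$scores)
  )
}

#' Serialize personas to JSON
#'
#' @param gallery A `persona_gallery`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_personas <- function(gallery, path) {
  jsonlite::write_json(
    list(
      personas = lapply(gallery$personas, persona_to_list),
      skipped = gallery$skipped
    ),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}
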