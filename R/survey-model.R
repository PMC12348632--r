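#' Construct a best-worst survey dataset
#'
#' Bundles respondent records with the attribute set and demographic schema
#' they refer to. Records are one row per respondent with a best pick, a
#' worst pick and the demographic answers; reading is non-destructive, so a
#' freshly constructed dataset may still contain records that
#' [clean_responses()] will remove (missing or contradictory picks, unknown
#' attribute tokens, duplicated ids).
#'
#' @param records Data frame with columns `respondent_id`, `best`, `worst`
#'   (attribute ids; `NA` for no answer) and one column per schema variable.
#' @param attributes An [attribute_set()].
#' @param schema A [demographic_schema()].
#' @param provenance Free-text origin of the data (file path or a simulation
#'   seed line).
#'
#' @return An object of class `bws_dataset`.
#' @export
bws_dataset <- function(records, attributes = qol_attributes(),
                        schema = qol_schema(), provenance = "in-memory") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  required <- c("respondent_id", "best", "worst", schema_variables(schema))
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop_bwsqol(
      paste0("records are missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      "bwsqol_schema_error"
    )
  }
  records <- records[required]
  for (col in required) records[[col]] <- as.character(records[[col]])
  # blank demographics are the PNR sentinel; blank picks are missing answers
  for (v in schema_variables(schema)) {
    x <- records[[v]]
    x[is.na(x) | !nzchar(x)] <- PNR
    records[[v]] <- x
  }
  for (col in c("best", "worst")) {
    x <- records[[col]]
    x[!is.na(x) & !nzchar(x)] <- NA_character_
    records[[col]] <- x
  }
  rownames(records) <- NULL
  structure(
    list(attributes = attributes, schema = schema, records = records,
         provenance = provenance),
    class = "bws_dataset"
  )
}

#' @export
print.bws_dataset <- function(x, ...) {
  cat("Best-worst survey dataset: ", nrow(x$records), " records, ",
      nrow(x$attributes), " attributes\n", sep = "")
  cat("provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Number of records in a dataset
#' @param dataset A [bws_dataset()].
#' @return Integer record count.
#' @export
n_records <- function(dataset) nrow(dataset$records)

#' Read respondent-level survey records from delimited text
#'
#' Expects a header row naming `respondent_id`, `best`, `worst` and every
#' schema variable. Reading is non-destructive: rows with blank picks or
#' attribute tokens outside the attribute set are carried through verbatim
#' for [clean_responses()] to count and remove; blank demographic cells
#' become the [PNR] sentinel; unknown demographic categories are preserved.
#'
#' @param path Path to a UTF-8 delimited text file.
#' @param schema A [demographic_schema()] naming the demographic columns.
#' @param attributes The [attribute_set()] the best/worst columns refer to.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#'
#' @return A [bws_dataset()] with one record per data row.
#' @export
read_responses <- function(path, schema = qol_schema(),
                           attributes = qol_attributes(), delim = ",") {
  if (!file.exists(path)) {
    stop_bwsqol(paste0("cannot read survey file: ", path), "bwsqol_io_error")
  }
  raw <- utils::read.table(
    path, header = TRUE, sep = delim, quote = "\"",
    colClasses = "character", check.names = FALSE,
    stringsAsFactors = FALSE, na.strings = character(0),
    fileEncoding = "UTF-8"
  )
  required <- c("respondent_id", "best", "worst", schema_variables(schema))
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop_bwsqol(
      paste0("file '", path, "' is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      "bwsqol_schema_error"
    )
  }
  bws_dataset(raw, attributes = attributes, schema = schema, provenance = path)
}

#' Write a dataset back to delimited text
#'
#' Inverse of [read_responses()]: the written file round-trips losslessly
#' (missing picks become blank cells, the [PNR] sentinel is written
#' verbatim).
#'
#' @param dataset A [bws_dataset()].
#' @param path Output file path.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return Invisibly, `path`.
#' @export
write_dataset <- function(dataset, path, delim = ",") {
  ok <- tryCatch({
    utils::write.table(
      dataset$records, path, sep = delim, qmethod = "double",
      row.names = FALSE, na = "", quote = TRUE, fileEncoding = "UTF-8"
    )
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop_bwsqol(paste0("cannot write dataset to: ", path), "bwsqol_io_error")
  }
  invisible(path)
}

#' Remove incomplete and logically inconsistent responses
#'
#' Applies the response-quality rules that take a raw survey file to the
#' valid analysis set, counting each removed record under exactly one reason,
#' in this order:
#' \describe{
#'   \item{`incomplete_choice`}{best or worst pick missing;}
#'   \item{`unknown_attribute`}{best or worst token outside the attribute set;}
#'   \item{`contradictory_choice`}{the same attribute picked as both best and
#'     worst;}
#'   \item{`duplicate_respondent`}{a respondent id already seen (the first
#'     occurrence is kept).}
#' }
#' Demographic non-response ([PNR]) is never grounds for removal.
#'
#' @param dataset A [bws_dataset()].
#' @return A list with components `dataset` (the cleaned [bws_dataset()]) and
#'   `report` (a `cleaning_report`: `n_raw`, `n_valid` and the per-reason
#'   removal counts, which always reconcile as
#'   `n_raw = n_valid + sum(removed_by_reason)`).
#' @export
clean_responses <- function(dataset) {
  rec <- dataset$records
  ids <- dataset$attributes$id
  n_raw <- nrow(rec)
  reason <- rep(NA_character_, n_raw)

  incomplete <- is.na(rec$best) | is.na(rec$worst)
  reason[incomplete] <- "incomplete_choice"

  unknown <- is.na(reason) & (!(rec$best %in% ids) | !(rec$worst %in% ids))
  reason[unknown] <- "unknown_attribute"

  contradictory <- is.na(reason) & rec$best == rec$worst
  reason[contradictory] <- "contradictory_choice"

  keep <- is.na(reason)
  dup <- keep & duplicated(ifelse(keep, rec$respondent_id, NA_character_), incomparables = NA)
  reason[dup] <- "duplicate_respondent"
  keep <- is.na(reason)

  report <- structure(
    list(
      n_raw = n_raw,
      n_valid = sum(keep),
      removed_by_reason = list(
        incomplete_choice = sum(incomplete),
        contradictory_choice = sum(contradictory),
        unknown_attribute = sum(unknown),
        duplicate_respondent = sum(dup)
      )
    ),
    class = "cleaning_report"
  )
  if (report$n_valid == 0L) {
    stop_bwsqol("no valid responses remain after cleaning", "bwsqol_empty_analysis")
  }
  cleaned <- dataset
  cleaned$records <- rec[keep, , drop = FALSE]
  rownames(cleaned$records) <- NULL
  list(dataset = cleaned, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Cleaning report: ", x$n_raw, " raw -> ", x$n_valid, " valid\n", sep = "")
  for (r in names(x$removed_by_reason)) {
    cat("  ", r, ": ", x$removed_by_reason[[r]], "\n", sep = "")
  }
  invisible(x)
}

#' Serialize a cleaning report to JSON
#'
#' @param report A `cleaning_report` from [clean_responses()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cleaning_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# TRUE when every record would survive clean_responses() unchanged
dataset_is_clean <- function(dataset) {
  rec <- dataset$records
  ids <- dataset$attributes$id
  if (nrow(rec) == 0L) return(TRUE)
  !any(is.na(rec$best) | is.na(rec$worst)) &&
    all(rec$best %in% ids) && all(rec$worst %in% ids) &&
    !any(rec$best == rec$worst) && !anyDuplicated(rec$respondent_id)
}

assert_cleaned <- function(dataset) {
  if (nrow(dataset$records) == 0L) {
    stop_bwsqol("dataset contains no records", "bwsqol_empty_analysis")
  }
  if (!dataset_is_clean(dataset)) {
    stop_bwsqol(
      "dataset contains records that clean_responses() would remove; clean it first",
      "bwsqol_not_cleaned"
    )
  }
  invisible(dataset)
}
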