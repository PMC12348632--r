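#' Define the attribute set of a best-worst scaling task
#'
#' An attribute set is the ordered list of items shown to every respondent in
#' a full-profile best-worst (MaxDiff) task. Each attribute has a short unique
#' id used in data files and a display label used in tables and reports.
#'
#' @param ids Character vector of unique, non-empty attribute ids.
#' @param labels Character vector of display labels, same length as `ids`.
#'
#' @return An object of class `attribute_set`: a data frame with columns
#'   `id` and `label`, one row per attribute, in presentation order.
#' @seealso [qol_attributes()] for the default six quality-of-life attributes.
#' @export
#' @examples
#' attribute_set(c("a", "b", "c"), c("Alpha", "Beta", "Gamma"))
attribute_set <- function(ids, labels = ids) {
  ids <- as.character(ids)
  labels <- as.character(labels)
  if (length(ids) == 0L) stop("attribute set must contain at least one attribute")
  if (anyDuplicated(ids)) stop("attribute ids must be unique")
  if (any(!nzchar(ids))) stop("attribute ids must be non-empty")
  if (length(labels) != length(ids)) stop("`labels` must match `ids` in length")
  structure(
    data.frame(id = ids, label = labels, stringsAsFactors = FALSE),
    class = c("attribute_set", "data.frame")
  )
}

#' Six quality-of-life attributes
#'
#' The default attribute set: the six interacting quality-of-life factors
#' elicited from low-income community residents (spiritual well-being, food
#' security, health care, social connections, economic opportunity, community
#' assets), in the presentation order used throughout the package.
#'
#' @return An [attribute_set()] with six attributes.
#' @export
qol_attributes <- function() {
  attribute_set(
    ids = c("spiritual", "food", "health", "social", "economic", "community"),
    labels = c(
      "Spiritual Well-being", "Food Security", "Health Care",
      "Social Connections", "Economic Opportunity", "Community Assets"
    )
  )
}

#' @export
print.attribute_set <- function(x, ...) {
  cat("Attribute set (", nrow(x), " attributes)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

attribute_labels <- function(attributes, ids) {
  attributes$label[match(ids, attributes$id)]
}
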