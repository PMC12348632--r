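#' Best/worst selection counts
#'
#' Container for the per-attribute best and worst selection frequencies of a
#' full-profile best-worst task. Both columns sum to the number of valid
#' respondents (each respondent contributes exactly one best and one worst
#' pick).
#'
#' @param best,worst Non-negative integer vectors, one entry per attribute.
#' @param attributes An [attribute_set()] aligned with `best`/`worst`.
#'
#' @return A `bws_counts` object: data frame with columns `attribute_id`,
#'   `label`, `best`, `worst`; attribute `n_valid`.
#' @export
#' @examples
#' bws_counts(c(70, 22, 52, 10, 53, 6), c(22, 8, 7, 100, 18, 58))
bws_counts <- function(best, worst, attributes = qol_attributes()) {
  best <- as.integer(best)
  worst <- as.integer(worst)
  J <- nrow(attributes)
  if (length(best) != J || length(worst) != J) {
    stop_bwsqol("`best` and `worst` must have one entry per attribute",
                "bwsqol_domain_error")
  }
  if (any(best < 0) || any(worst < 0)) {
    stop_bwsqol("counts must be non-negative", "bwsqol_domain_error")
  }
  if (sum(best) != sum(worst)) {
    stop_bwsqol("sum(best) must equal sum(worst): every respondent makes one of each pick",
                "bwsqol_domain_error")
  }
  structure(
    data.frame(attribute_id = attributes$id, label = attributes$label,
               best = best, worst = worst, stringsAsFactors = FALSE),
    n_valid = sum(best),
    class = c("bws_counts", "data.frame")
  )
}

#' Count best and worst choices in a dataset
#'
#' @param dataset A cleaned [bws_dataset()].
#' @return A [bws_counts()] with `n_valid` equal to the record count.
#' @export
count_choices <- function(dataset) {
  assert_cleaned(dataset)
  ids <- dataset$attributes$id
  best <- as.integer(table(factor(dataset$records$best, levels = ids)))
  worst <- as.integer(table(factor(dataset$records$worst, levels = ids)))
  bws_counts(best, worst, dataset$attributes)
}

#' Best-minus-worst scores
#'
#' The counting-analysis score of each attribute: the number of times it was
#' picked best minus the number of times it was picked worst. Scores always
#' sum to zero across attributes.
#'
#' @param counts A [bws_counts()].
#' @return Named integer vector (names are attribute ids).
#' @export
bw_scores <- function(counts) {
  stats::setNames(counts$best - counts$worst, counts$attribute_id)
}

#' Mean best-minus-worst scores
#'
#' B-W scores divided by the number of valid respondents, rounded
#' half-away-from-zero to `digits` decimals; bounded in \[-1, 1\].
#'
#' @param bw Integer B-W score vector.
#' @param n_valid Number of valid respondents (>= 1).
#' @param digits Decimal places (default 3, the conventional table precision).
#' @return Numeric vector, same names as `bw`.
#' @export
mean_bw_scores <- function(bw, n_valid, digits = 3) {
  if (!is.numeric(n_valid) || length(n_valid) != 1L || n_valid < 1) {
    stop_bwsqol("`n_valid` must be a single count >= 1", "bwsqol_domain_error")
  }
  round_half_away(bw / n_valid, digits)
}

#' Normalized relative weights
#'
#' Rescales B-W scores to a 0-100 importance scale: each score is shifted by
#' the minimum score and expressed as a percentage share of the shifted
#' total, so the least-preferred attribute gets exactly 0 and the weights sum
#' to 100 (up to rounding). If all scores are equal the shares are undefined
#' and the uniform weight `100/J` is returned for every attribute.
#'
#' @param bw Integer B-W score vector (>= 2 attributes).
#' @param digits Decimal places (default 2).
#' @return Numeric vector of percentages, same names as `bw`.
#' @export
#' @examples
#' normalized_weights(c(48, 14, 45, -90, 35, -52))
normalized_weights <- function(bw, digits = 2) {
  if (length(bw) < 2L) {
    stop_bwsqol("normalized weights need at least 2 attributes", "bwsqol_domain_error")
  }
  if (all(bw == bw[1L])) {
    return(stats::setNames(rep(round_half_away(100 / length(bw), digits), length(bw)),
                           names(bw)))
  }
  shifted <- bw - min(bw)
  round_half_away(100 * shifted / sum(shifted), digits)
}

#' Best-worst scaling score table
#'
#' The full counting-analysis summary: best/worst frequencies, B-W score,
#' mean B-W, normalized relative weight and rank for every attribute. Ranks
#' are by B-W descending; ties broken by best count descending, then by
#' declared attribute order, so the table is deterministic.
#'
#' @param x A cleaned [bws_dataset()] or a [bws_counts()].
#' @param ... Unused.
#' @return A `bws_score_table`: data frame with columns `attribute_id`,
#'   `label`, `best`, `worst`, `bw`, `mean_bw`, `weight`, `rank`; attribute
#'   `n_valid`.
#' @export
bws_score_table <- function(x, ...) UseMethod("bws_score_table")

#' @rdname bws_score_table
#' @export
bws_score_table.bws_dataset <- function(x, ...) {
  bws_score_table(count_choices(x))
}

#' @rdname bws_score_table
#' @export
bws_score_table.bws_counts <- function(x, ...) {
  n_valid <- attr(x, "n_valid")
  bw <- bw_scores(x)
  out <- data.frame(
    attribute_id = x$attribute_id,
    label = x$label,
    best = x$best,
    worst = x$worst,
    bw = as.integer(bw),
    mean_bw = mean_bw_scores(bw, n_valid),
    weight = normalized_weights(bw),
    stringsAsFactors = FALSE
  )
  ord <- order(-out$bw, -out$best, seq_len(nrow(out)))
  out$rank <- integer(nrow(out))
  out$rank[ord] <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, n_valid = n_valid,
            class = c("bws_score_table", "data.frame"))
}

#' @export
print.bws_score_table <- function(x, ...) {
  cat("Best-worst score table (n = ", attr(x, "n_valid"), ")\n", sep = "")
  shown <- data.frame(
    Variables = x$label,
    `Best Frequency` = x$best,
    `Worst Frequency` = x$worst,
    `B-W` = x$bw,
    `Mean (B-W)` = formatC(x$mean_bw, format = "f", digits = 3),
    `Normalized Relative Weights (%)` = formatC(x$weight, format = "f", digits = 2),
    Rank = x$rank,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  print.data.frame(shown, row.names = FALSE)
  invisible(x)
}

#' Serialize a score table to CSV
#'
#' Column names follow the conventional published layout: `Variables`,
#' `Best Frequency`, `Worst Frequency`, `B-W`, `Mean (B-W)`,
#' `Normalized Relative Weights (%)`.
#'
#' @param x A `bws_score_table`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_score_table <- function(x, path) {
  out <- data.frame(
    Variables = x$label,
    `Best Frequency` = x$best,
    `Worst Frequency` = x$worst,
    `B-W` = x$bw,
    `Mean (B-W)` = formatC(x$mean_bw, format = "f", digits = 3),
    `Normalized Relative Weights (%)` = formatC(x$weight, format = "f", digits = 2),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Ranks implied by a single best/worst pick
#'
#' Completes a respondent's partial order into a full rank vector: the best
#' attribute gets rank 1, the worst gets rank J, and the J-2 attributes in
#' between share the mid-rank `(J + 1) / 2` (the average of tied positions
#' 2..J-1). Rank sums are therefore always `J (J + 1) / 2`.
#'
#' @param best,worst Attribute indices in 1..J (distinct).
#' @param J Number of attributes (>= 2).
#' @return Numeric rank vector of length `J`.
#' @export
#' @examples
#' implied_ranks(1, 6, 6)  # 1, 3.5, 3.5, 3.5, 3.5, 6
implied_ranks <- function(best, worst, J) {
  if (J < 2L) stop_bwsqol("need at least 2 attributes", "bwsqol_domain_error")
  if (best == worst) stop_bwsqol("best and worst must differ", "bwsqol_domain_error")
  r <- rep((J + 1) / 2, J)
  r[best] <- 1
  r[worst] <- J
  r
}

# n x J implied-rank matrix of a cleaned dataset
implied_rank_matrix <- function(dataset) {
  ids <- dataset$attributes$id
  J <- length(ids)
  n <- nrow(dataset$records)
  b <- match(dataset$records$best, ids)
  w <- match(dataset$records$worst, ids)
  m <- matrix((J + 1) / 2, nrow = n, ncol = J, dimnames = list(NULL, ids))
  m[cbind(seq_len(n), b)] <- 1
  m[cbind(seq_len(n), w)] <- J
  m
}

#' Friedman test on best-worst implied ranks
#'
#' Tests whether the attributes differ in their within-respondent rank
#' distribution, treating each respondent as a block and using the rank
#' completion of [implied_ranks()]. Because the middle attributes are tied by
#' construction, the tie-corrected form of the Friedman chi-square is used:
#' \deqn{Q = (J-1) \sum_j (R_j - n(J+1)/2)^2 \Big/ (A - C)}
#' with \eqn{R_j} the column rank sums, \eqn{A = \sum_{ij} r_{ij}^2} and
#' \eqn{C = n J (J+1)^2 / 4}. Without ties this reduces to the classic
#' statistic. The p-value is the upper chi-square tail on J-1 degrees of
#' freedom.
#'
#' @param dataset A cleaned [bws_dataset()] with at least 3 attributes.
#' @return An object of classes `bws_friedman` and `htest` with components
#'   `statistic`, `parameter` (df), `p.value` and `n`.
#' @export
bws_friedman <- function(dataset) {
  assert_cleaned(dataset)
  J <- nrow(dataset$attributes)
  if (J < 3L) {
    stop_bwsqol("the Friedman test needs at least 3 attributes", "bwsqol_domain_error")
  }
  m <- implied_rank_matrix(dataset)
  n <- nrow(m)
  Rj <- colSums(m)
  A <- sum(m^2)
  C <- n * J * (J + 1)^2 / 4
  stat <- (J - 1) * sum((Rj - n * (J + 1) / 2)^2) / (A - C)
  df <- J - 1
  structure(
    list(
      statistic = c("Friedman chi-squared" = stat),
      parameter = c(df = df),
      p.value = stats::pchisq(stat, df, lower.tail = FALSE),
      n = n,
      method = "Friedman rank sum test on best-worst implied ranks (tie-corrected)",
      data.name = dataset$provenance
    ),
    class = c("bws_friedman", "htest")
  )
}
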