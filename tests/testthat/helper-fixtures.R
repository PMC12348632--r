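# Fixtures are built in code; nothing is loaded from disk.

qol_ids <- function() qol_attributes()$id

# Printed per-attribute selection frequencies of the six-attribute task
# (order: spiritual, food, health, social, economic, community), n = 213.
table2_best <- c(70, 22, 52, 10, 53, 6)
table2_worst <- c(22, 8, 7, 100, 18, 58)

# Deterministically pair best and worst picks so the marginals above are
# realized exactly with best != worst in every record.
pair_choices <- function(best_counts, worst_counts, ids = qol_ids()) {
  best <- rep(ids, best_counts)
  worst <- rep(ids, worst_counts)
  repeat {
    bad <- which(best == worst)
    if (!length(bad)) break
    i <- bad[1L]
    j <- which(worst != best[i] & best != worst[i])[1L]
    tmp <- worst[i]; worst[i] <- worst[j]; worst[j] <- tmp
  }
  data.frame(best = best, worst = worst, stringsAsFactors = FALSE)
}

# 213-record dataset realizing the printed best/worst frequencies.
table2_dataset <- function() {
  picks <- pair_choices(table2_best, table2_worst)
  n <- nrow(picks)
  records <- data.frame(
    respondent_id = sprintf("T2-%03d", seq_len(n)),
    picks,
    gender = PNR, age_group = PNR, race = PNR,
    education = PNR, relationship = PNR, employment = PNR,
    stringsAsFactors = FALSE
  )
  bws_dataset(records, provenance = "fixture: printed selection frequencies")
}

# Printed demographic counts (n = 217). Relationship rows sum to 207 in the
# source; the fixture completes the variable with a synthetic "Unreported"
# filler of 10 rows so every printed percentage has denominator 217.
table1_counts <- function() {
  list(
    gender = c("Female" = 124, "Male" = 84, "PNR" = 9),
    age_group = c("Young Adults (18-24)" = 5, "Adults (25-54)" = 114,
                  "Early Seniors (55-64)" = 44, "Seniors (65+)" = 43, "PNR" = 11),
    race = c("American Indian or Alaska Native" = 3,
             "Black or African American" = 88, "White" = 115, "PNR" = 11),
    education = c("Master's degree or higher" = 59, "Bachelor's degree" = 76,
                  "Associate's degree" = 25,
                  "Some college but did not complete degree" = 26,
                  "High school graduate or GED completed" = 9,
                  "Some high school" = 1, "PNR" = 21),
    relationship = c("Married and living with spouse" = 102,
                     "Married and not living with spouse" = 17, "Single" = 46,
                     "Committed relationship, not married" = 11, "Not sure" = 3,
                     "Unreported" = 10, "PNR" = 28),
    employment = c("Working full-time" = 133, "Working part-time" = 7,
                   "Retired" = 53, "Stay-at-home parent" = 8, "Unemployed" = 6,
                   "Disabled" = 1, "PNR" = 9)
  )
}

table1_dataset <- function() {
  counts <- table1_counts()
  n <- 217L
  demo <- lapply(counts, function(x) rep(names(x), x))
  records <- data.frame(
    respondent_id = sprintf("T1-%03d", seq_len(n)),
    best = "spiritual", worst = "social",
    demo, stringsAsFactors = FALSE
  )
  bws_dataset(records, provenance = "fixture: printed demographic counts")
}

# Random valid dataset: uniform choices, demographics from the survey
# marginals. Draws from the current RNG state.
random_valid_dataset <- function(n, ids = qol_ids()) {
  J <- length(ids)
  best <- sample.int(J, n, replace = TRUE)
  worst_off <- sample.int(J - 1L, n, replace = TRUE)
  worst <- (best + worst_off - 1L) %% J + 1L
  marg <- default_marginals()
  demo <- lapply(marg, function(m) sample(names(m), n, replace = TRUE, prob = m))
  records <- data.frame(
    respondent_id = sprintf("RV-%05d", seq_len(n)),
    best = ids[best], worst = ids[worst],
    demo, stringsAsFactors = FALSE
  )
  bws_dataset(records, provenance = "fixture: random valid records")
}

# Independent tie-corrected Friedman oracle: classic statistic divided by the
# tie-correction factor, with per-row tie groups enumerated explicitly.
friedman_oracle <- function(rank_matrix) {
  n <- nrow(rank_matrix); J <- ncol(rank_matrix)
  Rj <- colSums(rank_matrix)
  q0 <- 12 / (n * J * (J + 1)) * sum(Rj^2) - 3 * n * (J + 1)
  ties <- 0
  for (i in seq_len(n)) {
    for (t in table(rank_matrix[i, ])) ties <- ties + (t^3 - t)
  }
  cf <- 1 - ties / (n * J * (J^2 - 1))
  q0 / cf
}

# Kendall (bubble-sort) distance between two orderings given as permutations
kendall_distance <- function(a, b) {
  pos <- match(a, b)
  inv <- 0L
  for (i in seq_along(pos)) {
    inv <- inv + sum(pos[seq_len(i - 1L)] > pos[i])
  }
  inv
}
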