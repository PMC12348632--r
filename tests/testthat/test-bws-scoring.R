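test_that("choice counting matches a per-record brute-force recount", {
  withr::local_seed(71)
  d <- random_valid_dataset(1000)
  counts <- count_choices(d)
  expect_equal(attr(counts, "n_valid"), 1000L)
  expect_equal(sum(counts$best), 1000L)
  expect_equal(sum(counts$worst), 1000L)
  # independent oracle: iterate record by record
  ids <- qol_ids()
  b <- w <- setNames(integer(length(ids)), ids)
  for (i in seq_len(n_records(d))) {
    b[d$records$best[i]] <- b[d$records$best[i]] + 1L
    w[d$records$worst[i]] <- w[d$records$worst[i]] + 1L
  }
  expect_equal(setNames(counts$best, counts$attribute_id), b)
  expect_equal(setNames(counts$worst, counts$attribute_id), w)
})

test_that("unanimous picks concentrate the counts", {
  records <- data.frame(
    respondent_id = c("a", "b", "c"), best = "spiritual", worst = "social",
    gender = PNR, age_group = PNR, race = PNR, education = PNR,
    relationship = PNR, employment = PNR, stringsAsFactors = FALSE
  )
  counts <- count_choices(bws_dataset(records))
  expect_equal(counts$best[counts$attribute_id == "spiritual"], 3L)
  expect_equal(counts$worst[counts$attribute_id == "social"], 3L)
  expect_equal(sum(counts$best), 3L)
})

test_that("uncleaned or empty datasets are rejected by the scoring path", {
  d <- random_valid_dataset(4)
  d$records$worst[1] <- d$records$best[1]
  expect_error(count_choices(d), class = "bwsqol_not_cleaned")
  d0 <- random_valid_dataset(2)
  d0$records <- d0$records[0, , drop = FALSE]
  expect_error(count_choices(d0), class = "bwsqol_empty_analysis")
})

test_that("B-W scores, means and weights reproduce the printed table", {
  st <- bws_score_table(bws_counts(table2_best, table2_worst))
  expect_equal(st$bw, c(48L, 14L, 45L, -90L, 35L, -52L))
  expect_equal(sum(st$bw), 0L)
  expect_equal(st$weight, c(25.56, 19.26, 25.00, 0.00, 23.15, 7.04))
  # means consistent with n = 213 (two printed rows divide by ~217 instead
  # and are deliberately not pinned)
  means <- setNames(st$mean_bw, st$attribute_id)
  expect_equal(unname(means["spiritual"]), 0.225)
  expect_equal(unname(means["food"]), 0.066)
  expect_equal(unname(means["economic"]), 0.164)
  expect_equal(unname(means["social"]), -0.423)
  expect_equal(st$rank, c(1L, 4L, 2L, 6L, 3L, 5L))
})

test_that("mean scores validate and round half-away-from-zero", {
  expect_equal(mean_bw_scores(48, 213), 0.225)
  expect_equal(mean_bw_scores(0, 50), 0)
  expect_equal(mean_bw_scores(-90, 213), -0.423)
  expect_error(mean_bw_scores(5, 0), class = "bwsqol_domain_error")
})

test_that("normalized weights: min-shift share with a uniform degenerate case", {
  expect_equal(unname(normalized_weights(c(48, 14, 45, -90, 35, -52))),
               c(25.56, 19.26, 25.00, 0.00, 23.15, 7.04))
  expect_equal(unname(normalized_weights(c(5, -5))), c(100, 0))
  expect_equal(unname(normalized_weights(rep(3L, 6))), rep(16.67, 6))
  expect_error(normalized_weights(4L), class = "bwsqol_domain_error")
})

test_that("weights depend only on the B-W integers, means on n as well", {
  attrs <- attribute_set(c("a", "b"))
  st1 <- bws_score_table(bws_counts(c(5, 0), c(0, 5), attrs))   # n = 5
  st2 <- bws_score_table(bws_counts(c(7, 2), c(2, 7), attrs))   # n = 9, same bw
  expect_equal(st1$bw, st2$bw)
  expect_equal(st1$weight, st2$weight)
  expect_false(isTRUE(all.equal(st1$mean_bw, st2$mean_bw)))
})

test_that("sorting by bw, mean and weight yields the same permutation", {
  withr::local_seed(13)
  for (rep in 1:10) {
    d <- random_valid_dataset(80)
    st <- bws_score_table(d)
    expect_equal(order(-st$bw, -st$best, seq_len(nrow(st))), order(st$rank))
    expect_equal(order(-st$mean_bw, -st$bw), order(-st$bw, -st$mean_bw))
    expect_equal(order(-st$weight, -st$bw), order(-st$bw, -st$weight))
    expect_equal(min(st$weight), 0)
    expect_lt(abs(sum(st$weight) - 100), 0.02 + 1e-9)
  }
})

test_that("permuting the attribute order permutes rows but not values", {
  perm <- c(3L, 1L, 6L, 2L, 5L, 4L)
  attrs <- qol_attributes()
  permuted <- attribute_set(attrs$id[perm], attrs$label[perm])
  st1 <- bws_score_table(bws_counts(table2_best, table2_worst))
  st2 <- bws_score_table(bws_counts(table2_best[perm], table2_worst[perm],
                                    attributes = permuted))
  m1 <- st1[order(st1$attribute_id), c("bw", "mean_bw", "weight")]
  m2 <- st2[order(st2$attribute_id), c("bw", "mean_bw", "weight")]
  rownames(m1) <- rownames(m2) <- NULL
  expect_equal(m1, m2)
})

test_that("score table from records equals score table from marginal counts", {
  withr::local_seed(99)
  d <- random_valid_dataset(213)
  from_records <- bws_score_table(d)
  from_counts <- bws_score_table(count_choices(d))
  expect_identical(from_records, from_counts)
})

test_that("implied ranks complete the partial order with tied mid-ranks", {
  r <- implied_ranks(1, 6, 6)
  expect_equal(r, c(1, 3.5, 3.5, 3.5, 3.5, 6))
  expect_equal(implied_ranks(1, 3, 3), c(1, 2, 3))
  withr::local_seed(8)
  for (J in c(3, 4, 6, 9)) {
    bw <- sample.int(J, 2)
    expect_equal(sum(implied_ranks(bw[1], bw[2], J)), J * (J + 1) / 2)
  }
  expect_error(implied_ranks(2, 2, 6), class = "bwsqol_domain_error")
})

test_that("the Friedman statistic matches the closed form for unanimous data", {
  records <- data.frame(
    respondent_id = sprintf("u%02d", 1:20), best = "spiritual", worst = "social",
    gender = PNR, age_group = PNR, race = PNR, education = PNR,
    relationship = PNR, employment = PNR, stringsAsFactors = FALSE
  )
  d <- bws_dataset(records)
  ht <- bws_friedman(d)
  # closed form for n identical rows on J = 6: statistic = 5 n
  expect_equal(unname(ht$statistic), 100)
  expect_equal(unname(ht$parameter), 5)
  # row-exchangeability: permuting respondents changes nothing
  d2 <- d
  d2$records <- d$records[rev(seq_len(20)), ]
  rownames(d2$records) <- NULL
  expect_equal(unname(bws_friedman(d2)$statistic), unname(ht$statistic))
})

test_that("the Friedman statistic matches an independent tie-correction oracle", {
  withr::local_seed(55)
  for (rep in 1:25) {
    n <- sample(5:30, 1)
    d <- random_valid_dataset(n)
    ht <- bws_friedman(d)
    ids <- qol_ids()
    m <- matrix(3.5, n, 6)
    m[cbind(seq_len(n), match(d$records$best, ids))] <- 1
    m[cbind(seq_len(n), match(d$records$worst, ids))] <- 6
    expect_equal(unname(ht$statistic), friedman_oracle(m), tolerance = 1e-12)
    expect_equal(unname(ht$p.value),
                 pchisq(friedman_oracle(m), 5, lower.tail = FALSE))
  }
})

test_that("with three attributes (no ties) it agrees with stats::friedman.test", {
  withr::local_seed(66)
  attrs <- attribute_set(c("a", "b", "c"))
  schema <- demographic_schema(list(gender = c("Female", "Male")))
  n <- 40
  best <- sample.int(3, n, replace = TRUE)
  worst <- (best + sample.int(2, n, replace = TRUE) - 1L) %% 3L + 1L
  records <- data.frame(
    respondent_id = sprintf("x%02d", seq_len(n)),
    best = attrs$id[best], worst = attrs$id[worst],
    gender = "Female", stringsAsFactors = FALSE
  )
  d <- bws_dataset(records, attributes = attrs, schema = schema)
  ht <- bws_friedman(d)
  m <- matrix(2, n, 3)
  m[cbind(seq_len(n), best)] <- 1
  m[cbind(seq_len(n), worst)] <- 3
  ref <- stats::friedman.test(m)
  expect_equal(unname(ht$statistic), unname(ref$statistic), tolerance = 1e-12)
  expect_equal(unname(ht$p.value), unname(ref$p.value), tolerance = 1e-12)
})

test_that("the tie-corrected statistic is calibrated under the null", {
  withr::local_seed(77)
  stats <- replicate(200, {
    d <- random_valid_dataset(120)
    unname(bws_friedman(d)$statistic)
  })
  # null mean approximately equals the degrees of freedom
  expect_lt(abs(mean(stats) - 5), 0.7)
})

test_that("fewer than three attributes is a domain error for the test", {
  attrs <- attribute_set(c("a", "b"))
  schema <- demographic_schema(list(gender = c("F", "M")))
  records <- data.frame(respondent_id = c("1", "2"), best = "a", worst = "b",
                        gender = "F", stringsAsFactors = FALSE)
  d <- bws_dataset(records, attributes = attrs, schema = schema)
  expect_error(bws_friedman(d), class = "bwsqol_domain_error")
})
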