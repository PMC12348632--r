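test_that("identical config and seed give byte-identical datasets", {
  cfg <- bws_sim_preset("survey", n = 213, seed = 42,
                        incomplete_rate = 0.05, contradictory_rate = 0.02)
  s1 <- generate_bws_data(cfg)
  s2 <- generate_bws_data(cfg)
  expect_identical(s1$dataset$records, s2$dataset$records)
  expect_identical(s1$ground_truth, s2$ground_truth)
  s3 <- generate_bws_data(bws_sim_preset("survey", n = 213, seed = 43,
                                         incomplete_rate = 0.05,
                                         contradictory_rate = 0.02))
  expect_false(identical(s1$dataset$records, s3$dataset$records))
})

test_that("degenerate marginals are deterministic", {
  cfg <- bws_sim_preset("survey", n = 50, seed = 1)
  cfg$demographic_marginals$gender <- c("Female" = 1.0)
  sim <- generate_bws_data(cfg)
  expect_true(all(sim$dataset$records$gender == "Female"))
})

test_that("sampled demographics converge to the configured marginals", {
  withr::local_seed(101)
  cfg <- bws_sim_preset("survey", n = 1)
  demo <- sample_demographics(cfg, 10000)
  p <- default_marginals()$gender["Female"]
  se <- sqrt(p * (1 - p) / 10000)
  expect_lt(abs(mean(demo$gender == "Female") - p), 3 * se)
})

test_that("equal utilities make every attribute equally likely best", {
  withr::local_seed(103)
  draws <- t(replicate(12000, sample_choice(rep(0, 6))))
  shares <- tabulate(draws[, 1], 6) / 12000
  se <- sqrt((1 / 6) * (5 / 6) / 12000)
  expect_true(all(abs(shares - 1 / 6) < 3 * se + 1e-12))
  expect_true(all(draws[, 1] != draws[, 2]))  # best never equals worst
})

test_that("dominant utilities pin the choice", {
  withr::local_seed(107)
  draws <- t(replicate(500, sample_choice(c(20, 0, 0, 0, 0, -20))))
  expect_true(all(draws[, 1] == 1))
  expect_true(all(draws[, 2] == 6))
})

test_that("best-choice shares match the softmax oracle", {
  withr::local_seed(109)
  u <- c(1, 0, -1, 0, 0, 0)
  n <- 50000
  draws <- t(replicate(n, sample_choice(u)))
  softmax <- exp(u) / sum(exp(u))
  shares <- tabulate(draws[, 1], 6) / n
  for (j in 1:6) {
    se <- sqrt(softmax[j] * (1 - softmax[j]) / n)
    expect_lt(abs(shares[j] - softmax[j]), 3 * se + 1e-12)
  }
})

test_that("analytic choice shares are a proper distribution pair", {
  u <- .5 * c(2, 1, 0, -1, -2, 0)
  s <- bws_choice_shares(u)
  expect_equal(sum(s$best), 1)
  expect_equal(sum(s$worst), 1)
  expect_equal(sum(s$bw), 0)
  # Gumbel-max generation agrees with the analytic worst shares too
  cfg <- sim_config(n_respondents = 40000, seed = 211, base_utilities = u)
  sim <- generate_bws_data(cfg)
  ids <- cfg$attributes$id
  worst_share <- tabulate(match(sim$dataset$records$worst, ids), 6) / 40000
  for (j in 1:6) {
    se <- sqrt(s$worst[j] * (1 - s$worst[j]) / 40000)
    expect_lt(abs(worst_share[j] - s$worst[j]), 4 * se + 1e-12)
  }
})

test_that("error-free generation survives cleaning unchanged", {
  sim <- generate_bws_data(bws_sim_preset("survey", n = 213, seed = 7))
  out <- clean_responses(sim$dataset)
  expect_equal(out$report$n_valid, 213L)
  expect_equal(sum(unlist(out$report$removed_by_reason)), 0L)
  expect_true(all(sim$ground_truth$corruption == "none"))
})

test_that("cleaning counts reconcile exactly with injected corruption labels", {
  sim <- generate_bws_data(sim_config(
    n_respondents = 2000, seed = 31,
    incomplete_rate = 0.10, contradictory_rate = 0.05
  ))
  out <- clean_responses(sim$dataset)
  labels <- table(sim$ground_truth$corruption)
  expect_equal(out$report$removed_by_reason$incomplete_choice,
               unname(labels["incomplete"]))
  expect_equal(out$report$removed_by_reason$contradictory_choice,
               unname(labels["contradictory"]))
  expect_equal(out$report$n_valid, unname(labels["none"]))
  # survivors are exactly the uncorrupted respondents
  expect_setequal(out$dataset$records$respondent_id,
                  sim$ground_truth$respondent_id[sim$ground_truth$corruption == "none"])
})

test_that("segment shifts apply to exactly the matching respondents", {
  cfg <- sim_config(
    n_respondents = 500, seed = 61, base_utilities = rep(0, 6),
    segments = list(segment_spec(list(gender = "Female"), c(3, 0, 0, 0, 0, -3)))
  )
  sim <- generate_bws_data(cfg)
  U <- attr(sim$ground_truth, "utilities")
  female <- sim$dataset$records$gender == "Female"
  expect_true(all(U[female, 1] == 3))
  expect_true(all(U[!female, 1] == 0))
  # shifted segment strongly prefers the boosted attribute
  share <- mean(sim$dataset$records$best[female] == "spiritual")
  expect_gt(share, 0.5)
})

test_that("sample orderings converge to the utility ordering as n grows", {
  u <- c(1.5, 0.9, 0.3, -0.3, -0.9, -1.5)
  true_order <- order(-u)
  dist_at <- function(n, seed) {
    sim <- generate_bws_data(sim_config(n_respondents = n, seed = seed,
                                        base_utilities = u))
    st <- bws_score_table(sim$dataset)
    kendall_distance(order(st$rank), true_order)
  }
  expect_lte(dist_at(200, 71), 1)
  expect_equal(dist_at(2000, 72), 0)
  expect_equal(dist_at(20000, 73), 0)
})

test_that("the frozen survey utilities are the maximum-likelihood fit", {
  u <- fit_bws_utilities(setNames(table2_best, qol_ids()), table2_worst)
  preset <- bws_sim_preset("survey")
  expect_equal(unname(u), unname(preset$base_utilities), tolerance = 1e-4)
  expect_equal(names(u), preset$attributes$id)
})

test_that("the survey preset reproduces its analytic expectations", {
  preset <- bws_sim_preset("survey")
  s <- bws_choice_shares(preset$base_utilities)
  withr::local_seed(113)
  reps <- 60
  best_counts <- matrix(0, reps, 6)
  for (r in seq_len(reps)) {
    sim <- generate_bws_data(bws_sim_preset("survey", n = 213, seed = 5000 + r))
    best_counts[r, ] <- tabulate(match(sim$dataset$records$best, qol_ids()), 6)
  }
  for (j in 1:6) {
    se <- sqrt(213 * s$best[j] * (1 - s$best[j]) / reps)
    expect_lt(abs(mean(best_counts[, j]) - 213 * s$best[j]), 3 * se + 1e-9)
  }
  # expected B-W ordering agrees with the printed scores on all well-separated
  # pairs (the near-tied top pair is discussed in the vignette)
  printed_bw <- table2_best - table2_worst
  expect_equal(kendall_distance(order(-s$bw), order(-printed_bw)), 1)
})

test_that("invalid configs are rejected with every offending field named", {
  err <- tryCatch(
    sim_config(n_respondents = 0, incomplete_rate = -0.1,
               base_utilities = rep(0, 4)),
    bwsqol_config_error = identity
  )
  expect_s3_class(err, "bwsqol_config_error")
  msg <- conditionMessage(err)
  expect_match(msg, "n_respondents")
  expect_match(msg, "incomplete_rate")
  expect_match(msg, "base_utilities")
  expect_error(sim_config(10, incomplete_rate = 0.6, contradictory_rate = 0.5),
               class = "bwsqol_config_error")
})

test_that("configs round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    preset = "survey", n_respondents = 99, seed = 8, contradictory_rate = 0.02,
    segments = list(list(selector = list(gender = list("Female")),
                         shift = c(1, 0, 0, 0, 0, -1)))
  ), path)
  cfg <- sim_config_from_yaml(path)
  expect_equal(cfg$n_respondents, 99)
  expect_equal(cfg$seed, 8L)
  expect_equal(cfg$contradictory_rate, 0.02)
  expect_equal(cfg$base_utilities, unname(bws_sim_preset("survey")$base_utilities))
  expect_length(cfg$segments, 1L)
  expect_equal(cfg$segments[[1]]$shift[1], 1)
})
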