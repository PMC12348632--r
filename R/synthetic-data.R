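# Synthetic respondent generator: latent-utility best-worst choices with
# segment-dependent shifts, realistic demographic marginals and injectable
# response errors. Ground truth never flows into the analysis modules.

# Demographic counts of the source survey's descriptive table (n = 217 with
# item non-response kept as PNR). Relationship rows sum to 207 in the source;
# marginals normalize within the variable.
.survey_demographic_counts <- list(
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
                   "PNR" = 28),
  employment = c("Working full-time" = 133, "Working part-time" = 7,
                 "Retired" = 53, "Stay-at-home parent" = 8, "Unemployed" = 6,
                 "Disabled" = 1, "PNR" = 9)
)

# Base utilities of the survey preset (attribute order: spiritual, food,
# health, social, economic, community). Centered maximum-likelihood fit of
# the sequential best-worst logit to the published selection frequencies
# (70/22, 22/8, 52/7, 10/100, 53/18, 6/58); reproducible via
# fit_bws_utilities(). Versioned constants: refitting is not done at run time.
.survey_base_utilities <- c(
  spiritual = 0.696142, food = 0.231448, health = 0.718833,
  social = -1.300794, economic = 0.533180, community = -0.878810
)

#' Default demographic marginals
#'
#' Category probabilities per demographic variable, including the [PNR]
#' non-response share, matching the marginal distribution observed in the
#' source quality-of-life survey (n = 217).
#'
#' @return Named list: per variable, a named probability vector summing to 1.
#' @export
default_marginals <- function() {
  lapply(.survey_demographic_counts, function(x) x / sum(x))
}

#' Declare a segment-specific utility shift
#'
#' Respondents matching the selector receive an additive shift on the latent
#' attribute utilities, producing segment-dependent priorities (e.g. a
#' retired segment valuing spiritual well-being more). Shifts of all matching
#' segment specs add up.
#'
#' @param selector Named list of demographic conditions, as in
#'   [persona_rule()]: variable -> acceptable categories.
#' @param shift Numeric vector of per-attribute utility deltas (length =
#'   number of attributes).
#' @return A `segment_spec`.
#' @export
segment_spec <- function(selector, shift) {
  if (!is.list(selector) || length(selector) == 0L || is.null(names(selector))) {
    stop_bwsqol("`selector` must be a non-empty named list", "bwsqol_domain_error")
  }
  structure(list(selector = lapply(selector, as.character), shift = as.numeric(shift)),
            class = "segment_spec")
}

#' Configure a synthetic survey simulation
#'
#' @param n_respondents Number of respondents to draw (>= 1).
#' @param seed Integer root seed; identical (config, seed) pairs generate
#'   byte-identical datasets.
#' @param attributes An [attribute_set()].
#' @param schema A [demographic_schema()].
#' @param demographic_marginals Named list of per-variable category
#'   probability vectors (must each sum to 1; categories may include [PNR]).
#' @param base_utilities Numeric latent utilities, one per attribute
#'   (location-free: only differences matter).
#' @param segments List of [segment_spec()] utility shifts.
#' @param incomplete_rate Probability a respondent's worst pick is blanked
#'   (simulating an abandoned item); in \[0, 1).
#' @param contradictory_rate Probability the worst pick is overwritten with
#'   the best pick (a logically inconsistent response); in \[0, 1).
#'   Corruption events are mutually exclusive per respondent, so cleaning
#'   counts reconcile exactly with the generator's ground-truth labels.
#' @return A validated `bws_sim_config`.
#' @export
sim_config <- function(n_respondents, seed = 1L,
                       attributes = qol_attributes(), schema = qol_schema(),
                       demographic_marginals = default_marginals(),
                       base_utilities = rep(0, nrow(attributes)),
                       segments = list(),
                       incomplete_rate = 0, contradictory_rate = 0) {
  config <- structure(
    list(
      n_respondents = n_respondents, seed = as.integer(seed),
      attributes = attributes, schema = schema,
      demographic_marginals = demographic_marginals,
      base_utilities = as.numeric(base_utilities), segments = segments,
      incomplete_rate = incomplete_rate, contradictory_rate = contradictory_rate
    ),
    class = "bws_sim_config"
  )
  validate_sim_config(config)
  config
}

validate_sim_config <- function(config) {
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)
  J <- nrow(config$attributes)
  if (!is.numeric(config$n_respondents) || length(config$n_respondents) != 1L ||
      is.na(config$n_respondents) || config$n_respondents < 1) {
    add("n_respondents: must be a single count >= 1")
  }
  if (length(config$base_utilities) != J || any(!is.finite(config$base_utilities))) {
    add("base_utilities: must be finite, one per attribute")
  }
  for (r in c("incomplete_rate", "contradictory_rate")) {
    v <- config[[r]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v >= 1) {
      add(paste0(r, ": must lie in [0, 1)"))
    }
  }
  if (is.numeric(config$incomplete_rate) && is.numeric(config$contradictory_rate) &&
      isTRUE(config$incomplete_rate + config$contradictory_rate >= 1)) {
    add("incomplete_rate + contradictory_rate: must be < 1")
  }
  vars <- schema_variables(config$schema)
  if (!setequal(names(config$demographic_marginals), vars)) {
    add("demographic_marginals: must name exactly the schema variables")
  } else {
    for (v in vars) {
      m <- config$demographic_marginals[[v]]
      if (is.null(names(m)) || any(!nzchar(names(m)))) {
        add(paste0("demographic_marginals$", v, ": categories must be named"))
        next
      }
      if (any(m < 0) || abs(sum(m) - 1) > 1e-9) {
        add(paste0("demographic_marginals$", v, ": probabilities must be >= 0 and sum to 1"))
      }
    }
  }
  for (i in seq_along(config$segments)) {
    s <- config$segments[[i]]
    if (!inherits(s, "segment_spec")) {
      add(paste0("segments[[", i, "]]: not a segment_spec"))
    } else if (length(s$shift) != J || any(!is.finite(s$shift))) {
      add(paste0("segments[[", i, "]]: shift must be finite, one per attribute"))
    }
  }
  if (length(problems)) {
    stop_bwsqol(
      paste0("invalid simulation config:\n  ", paste(problems, collapse = "\n  ")),
      "bwsqol_config_error"
    )
  }
  invisible(config)
}

#' @export
print.bws_sim_config <- function(x, ...) {
  cat("Simulation config: n = ", x$n_respondents, ", seed = ", x$seed,
      ", ", length(x$segments), " segment shift(s), rates (incomplete ",
      x$incomplete_rate, ", contradictory ", x$contradictory_rate, ")\n", sep = "")
  invisible(x)
}

#' Draw demographics from the configured marginals
#'
#' Each variable is drawn independently from its categorical marginal
#' (intersectional dependence is deliberately not modeled). Uses the current
#' RNG state; seed externally for reproducibility.
#'
#' @param config A `bws_sim_config`.
#' @param n Number of respondents to draw.
#' @return Data frame with one column per schema variable.
#' @export
sample_demographics <- function(config, n = 1) {
  out <- lapply(schema_variables(config$schema), function(v) {
    m <- config$demographic_marginals[[v]]
    sample(names(m), n, replace = TRUE, prob = m)
  })
  names(out) <- schema_variables(config$schema)
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Draw one best-worst choice from latent utilities
#'
#' Sequential maximum-difference choice: the best attribute is drawn with
#' probability proportional to `exp(u)` over all attributes, then the worst
#' is drawn with probability proportional to `exp(-u)` over the remaining
#' attributes, so best and worst always differ. Uses the current RNG state.
#'
#' @param utilities Numeric utility vector (>= 2 attributes).
#' @return Integer vector `c(best = i, worst = j)` of attribute indices.
#' @export
sample_choice <- function(utilities) {
  J <- length(utilities)
  if (J < 2L) stop_bwsqol("need at least 2 attributes", "bwsqol_domain_error")
  pb <- exp(utilities - max(utilities))
  best <- sample.int(J, 1L, prob = pb)
  pw <- exp(-(utilities - min(utilities)))
  pw[best] <- 0
  worst <- sample.int(J, 1L, prob = pw)
  c(best = best, worst = worst)
}

#' Analytic choice shares of the sequential best-worst model
#'
#' Exact marginal probabilities that each attribute is picked best and worst
#' under [sample_choice()]'s model, by summing over the best pick.
#'
#' @param utilities Numeric utility vector.
#' @return List with numeric vectors `best` and `worst` (each sums to 1) and
#'   `bw` (their difference: the expected per-respondent B-W contribution).
#' @export
bws_choice_shares <- function(utilities) {
  J <- length(utilities)
  pb <- exp(utilities - max(utilities))
  pb <- pb / sum(pb)
  en <- exp(-(utilities - min(utilities)))
  pw <- numeric(J)
  for (b in seq_len(J)) {
    rem <- setdiff(seq_len(J), b)
    pw[rem] <- pw[rem] + pb[b] * en[rem] / sum(en[rem])
  }
  names(pb) <- names(pw) <- names(utilities)
  list(best = pb, worst = pw, bw = pb - pw)
}

#' Fit sequential best-worst utilities to selection counts
#'
#' Maximum-likelihood calibration of the latent utilities of the sequential
#' best-worst model to observed per-attribute best and worst counts (both
#' margins jointly). The fitted vector is centered (utilities are
#' location-free). Used to derive the versioned constants behind
#' [bws_sim_preset()].
#'
#' @param best,worst Integer count vectors, one per attribute.
#' @return Named numeric utility vector (names from `names(best)` if set).
#' @export
fit_bws_utilities <- function(best, worst) {
  J <- length(best)
  if (length(worst) != J || J < 2L) {
    stop_bwsqol("`best` and `worst` must be equal-length vectors (>= 2)",
                "bwsqol_domain_error")
  }
  nll <- function(u_free) {
    u <- c(u_free, 0)
    s <- bws_choice_shares(u)
    -(sum(best * log(s$best)) + sum(worst * log(s$worst)))
  }
  fit <- stats::optim(rep(0, J - 1L), nll, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 1000))
  u <- c(fit$par, 0)
  u <- u - mean(u)
  names(u) <- names(best)
  u
}

# rows of the utility matrix matching a segment selector
selector_matches <- function(demographics, selector) {
  idx <- rep(TRUE, nrow(demographics))
  for (v in names(selector)) {
    idx <- idx & demographics[[v]] %in% selector[[v]]
  }
  idx
}

#' Generate a synthetic best-worst survey dataset
#'
#' For each respondent: demographics are drawn from the configured marginals;
#' latent utilities are the base utilities plus the shifts of every matching
#' [segment_spec()]; a best-worst pick is drawn by Gumbel-max sampling
#' (equivalent in distribution to [sample_choice()]); finally response errors
#' are injected -- with probability `incomplete_rate` the worst pick is
#' blanked, else with probability `contradictory_rate` it is overwritten with
#' the best pick. Every manipulation is recorded in the ground truth, which
#' exists for validation only and must never feed the analysis path.
#'
#' All randomness comes from one stream seeded with `config$seed`; draws are
#' made column-wise in a fixed order, so identical configs give byte-identical
#' output.
#'
#' @param config A `bws_sim_config`.
#' @return A `bws_simulation`: list with `dataset` (a [bws_dataset()], possibly
#'   containing injected invalid records for [clean_responses()] to find) and
#'   `ground_truth` (data frame with `respondent_id`, `corruption`
#'   (none/incomplete/contradictory), `true_best`, `true_worst`; the n x J
#'   utility matrix is attached as attribute `utilities`).
#' @export
generate_bws_data <- function(config) {
  validate_sim_config(config)
  n <- as.integer(config$n_respondents)
  J <- nrow(config$attributes)
  ids <- config$attributes$id
  set.seed(config$seed)

  demographics <- sample_demographics(config, n)

  U <- matrix(rep(config$base_utilities, each = n), nrow = n,
              dimnames = list(NULL, ids))
  for (s in config$segments) {
    hit <- selector_matches(demographics, s$selector)
    if (any(hit)) U[hit, ] <- sweep(U[hit, , drop = FALSE], 2L, s$shift, `+`)
  }

  gumbel <- function() -log(-log(matrix(stats::runif(n * J), n, J)))
  best <- max.col(U + gumbel(), ties.method = "first")
  worst_score <- -U + gumbel()
  worst_score[cbind(seq_len(n), best)] <- -Inf
  worst <- max.col(worst_score, ties.method = "first")

  u_corrupt <- stats::runif(n)
  corruption <- rep("none", n)
  corruption[u_corrupt < config$incomplete_rate] <- "incomplete"
  corruption[u_corrupt >= config$incomplete_rate &
               u_corrupt < config$incomplete_rate + config$contradictory_rate] <-
    "contradictory"

  obs_best <- ids[best]
  obs_worst <- ids[worst]
  obs_worst[corruption == "incomplete"] <- NA_character_
  obs_worst[corruption == "contradictory"] <- obs_best[corruption == "contradictory"]

  respondent_id <- sprintf("R%05d", seq_len(n))
  records <- data.frame(
    respondent_id = respondent_id, best = obs_best, worst = obs_worst,
    demographics, stringsAsFactors = FALSE, check.names = FALSE
  )
  config_hash <- fnv1a32(paste(
    n, config$seed, paste(ids, collapse = ","),
    paste(signif(config$base_utilities, 10), collapse = ","),
    length(config$segments), config$incomplete_rate, config$contradictory_rate,
    sep = "|"
  ))
  dataset <- bws_dataset(
    records, attributes = config$attributes, schema = config$schema,
    provenance = sprintf("simulated: seed=%d n=%d config=%s",
                         config$seed, n, config_hash)
  )
  ground_truth <- data.frame(
    respondent_id = respondent_id, corruption = corruption,
    true_best = ids[best], true_worst = ids[worst],
    stringsAsFactors = FALSE
  )
  attr(ground_truth, "utilities") <- U
  structure(list(dataset = dataset, ground_truth = ground_truth),
            class = "bws_simulation")
}

#' @export
print.bws_simulation <- function(x, ...) {
  cat("Synthetic survey simulation\n")
  print(x$dataset)
  cat("corruption: ",
      paste(names(table(x$ground_truth$corruption)),
            table(x$ground_truth$corruption), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Ready-made simulation presets
#'
#' Two documented study designs:
#' \describe{
#'   \item{`"survey"`}{emulates the source quality-of-life telephone survey:
#'     demographic marginals from [default_marginals()] and base utilities
#'     calibrated by maximum likelihood to the published best/worst selection
#'     frequencies (see [fit_bws_utilities()]); no segment shifts. Default
#'     n = 213, the valid analysis set size.}
#'   \item{`"personas"`}{a segmented population exercising the
#'     characterization stage: the same base utilities plus documented
#'     segment shifts (retirees and women toward spiritual well-being and
#'     health care, full-time workers and men toward economic opportunity,
#'     unemployed and lower-education respondents toward food security and
#'     community assets), with flatter demographic marginals so that rarer
#'     segment conjunctions receive workable sample sizes. Default n = 2000.}
#' }
#'
#' @param name `"survey"` or `"personas"`.
#' @param n Number of respondents (defaults above).
#' @param seed Root seed.
#' @param incomplete_rate,contradictory_rate Response error rates
#'   (default 0).
#' @return A `bws_sim_config`.
#' @export
bws_sim_preset <- function(name = c("survey", "personas"), n = NULL, seed = 1L,
                           incomplete_rate = 0, contradictory_rate = 0) {
  name <- match.arg(name)
  if (name == "survey") {
    sim_config(
      n_respondents = n %||% 213,
      seed = seed,
      base_utilities = .survey_base_utilities,
      incomplete_rate = incomplete_rate,
      contradictory_rate = contradictory_rate
    )
  } else {
    low_ed <- education_groups()$low_education
    # order: spiritual, food, health, social, economic, community
    segments <- list(
      segment_spec(list(employment = "Retired"),
                   c(1.6, 0, 0.5, 0, -0.5, 0)),
      segment_spec(list(gender = "Female"),
                   c(0.5, 0, 0.9, 0, -0.4, 0)),
      segment_spec(list(gender = "Male"),
                   c(0, 0, 0, 0, 0.8, 0)),
      segment_spec(list(employment = "Working full-time"),
                   c(0, 0, 0.3, 0, 0.8, 0)),
      segment_spec(list(employment = "Unemployed"),
                   c(-0.5, 2.0, 0, 0, -0.5, 0.8)),
      segment_spec(list(education = low_ed),
                   c(-0.5, 0.8, 0, 0, -0.5, 0.5))
    )
    marginals <- list(
      gender = c("Female" = 0.55, "Male" = 0.42, "PNR" = 0.03),
      age_group = c("Young Adults (18-24)" = 0.05, "Adults (25-54)" = 0.50,
                    "Early Seniors (55-64)" = 0.20, "Seniors (65+)" = 0.20,
                    "PNR" = 0.05),
      race = c("American Indian or Alaska Native" = 0.05,
               "Black or African American" = 0.40, "White" = 0.50, "PNR" = 0.05),
      education = c("Master's degree or higher" = 0.20, "Bachelor's degree" = 0.20,
                    "Associate's degree" = 0.10,
                    "Some college but did not complete degree" = 0.20,
                    "High school graduate or GED completed" = 0.10,
                    "Some high school" = 0.05, "PNR" = 0.15),
      relationship = c("Married and living with spouse" = 0.40,
                       "Married and not living with spouse" = 0.05,
                       "Single" = 0.30, "Committed relationship, not married" = 0.10,
                       "Not sure" = 0.05, "PNR" = 0.10),
      employment = c("Working full-time" = 0.45, "Working part-time" = 0.05,
                     "Retired" = 0.25, "Stay-at-home parent" = 0.05,
                     "Unemployed" = 0.15, "Disabled" = 0.02, "PNR" = 0.03)
    )
    sim_config(
      n_respondents = n %||% 2000,
      seed = seed,
      base_utilities = .survey_base_utilities,
      demographic_marginals = marginals,
      segments = segments,
      incomplete_rate = incomplete_rate,
      contradictory_rate = contradictory_rate
    )
  }
}

#' Serialize simulation ground truth to JSON
#'
#' Writes the corruption labels and true picks (not the utility matrix) as a
#' sidecar for label-reconciliation checks.
#'
#' @param simulation A `bws_simulation`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(simulation, path) {
  jsonlite::write_json(simulation$ground_truth, path, auto_unbox = TRUE,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' Read a simulation config from YAML
#'
#' Recognized top-level keys: `n_respondents`, `seed`, `incomplete_rate`,
#' `contradictory_rate`, `preset` (applied first, then overridden by the
#' other keys), `base_utilities`, and `segments` (list of
#' `{selector: {variable: [categories]}, shift: [numbers]}`).
#'
#' @param path YAML file path.
#' @return A `bws_sim_config`.
#' @export
sim_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  base <- if (!is.null(y$preset)) {
    bws_sim_preset(y$preset)
  } else {
    sim_config(n_respondents = y$n_respondents %||% 213)
  }
  if (!is.null(y$n_respondents)) base$n_respondents <- y$n_respondents
  if (!is.null(y$seed)) base$seed <- as.integer(y$seed)
  if (!is.null(y$incomplete_rate)) base$incomplete_rate <- y$incomplete_rate
  if (!is.null(y$contradictory_rate)) base$contradictory_rate <- y$contradictory_rate
  if (!is.null(y$base_utilities)) base$base_utilities <- as.numeric(y$base_utilities)
  if (!is.null(y$segments)) {
    base$segments <- lapply(y$segments, function(s) {
      segment_spec(s$selector, as.numeric(s$shift))
    })
  }
  validate_sim_config(base)
  base
}
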