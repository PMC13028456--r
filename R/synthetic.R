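# Synthetic listing datasets with the statistical structure the update
# pipeline assumes: per-category log-normal daily prices whose medians
# follow the observed trend (higher prices for smaller patient
# populations), patient counts uniform within each category's bounds, and
# configurable fractions of per-treatment / per-season / non-derivable
# records so the exclusion rules have something to fire on.

#' Configuration for the synthetic listings generator
#'
#' Defaults emulate the published extraction: 372 drugs over fiscal years
#' 2015-2024, per-category target medians taken from the FY2015-2024
#' anchor row (placed at the midpoint of each anchor's truncation
#' preimage, so floored sample medians truncate back to the anchor),
#' uniform category weights, log-normal price noise with log-sd 0.6, and
#' small exclusion fractions (about 8% of records overall).
#'
#' @param seed Integer seed; mandatory, every draw is reproducible.
#' @param n_drugs Number of listing records to generate (default 372).
#' @param window Fiscal-year window (default `c(2015, 2024)`); see
#'   [parse_window()].
#' @param target_medians Numeric vector of 15 per-category target median
#'   daily prices (JPY), ordered as [patient_categories()]. The observed
#'   trend is medians decreasing as patient counts increase; a
#'   non-monotone vector draws a warning, not an error, because published
#'   anchor rows themselves contain local reversals.
#' @param weights Category sampling probabilities (length 15, sum 1).
#' @param dispersion Log-scale standard deviation of prices around the
#'   category median; 0 gives degenerate (exact-median) prices.
#' @param exclusion_fractions Named numeric: probabilities `per_treatment`,
#'   `per_season`, `not_derivable`.
#' @param patient_cap Sampling ceiling for the unbounded top category
#'   (default 10,000,000 patients).
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(seed,
                              n_drugs = 372L,
                              window = c(2015L, 2024L),
                              target_medians = NULL,
                              weights = NULL,
                              dispersion = 0.6,
                              exclusion_fractions = c(per_treatment = 0.005,
                                                      per_season = 0.003,
                                                      not_derivable = 0.07),
                              patient_cap = 1e7) {
  if (missing(seed) || length(seed) != 1 || is.na(suppressWarnings(
        as.integer(seed)))) {
    stop_marie("seed is mandatory and must be a single integer",
               class = "marie_validation_error")
  }
  ncat <- length(.category_labels)
  user_targets <- !is.null(target_medians)
  if (!user_targets) {
    target_medians <- anchor_preimage_midpoint(marie_table3()$anchor)
  }
  if (is.null(weights)) weights <- rep(1 / ncat, ncat)
  problems <- character(0)
  if (length(target_medians) != ncat || anyNA(target_medians) ||
      any(target_medians <= 0)) {
    problems <- c(problems, sprintf(
      "target_medians must be %d positive prices", ncat))
  }
  if (length(weights) != ncat || anyNA(weights) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8) {
    problems <- c(problems, sprintf(
      "weights must be %d non-negative probabilities summing to 1", ncat))
  }
  if (length(dispersion) != 1 || is.na(dispersion) || dispersion < 0) {
    problems <- c(problems, "dispersion must be a single number >= 0")
  }
  ef <- exclusion_fractions
  if (!all(c("per_treatment", "per_season", "not_derivable") %in% names(ef)) ||
      any(ef < 0) || sum(ef) >= 1) {
    problems <- c(problems, paste(
      "exclusion_fractions must name per_treatment, per_season,",
      "not_derivable, each >= 0, with sum < 1"))
  }
  if (length(n_drugs) != 1 || is.na(n_drugs) || n_drugs < 1) {
    problems <- c(problems, "n_drugs must be a positive integer")
  }
  if (length(patient_cap) != 1 || patient_cap <= .category_lowers[ncat]) {
    problems <- c(problems, "patient_cap must exceed the top category bound")
  }
  if (length(problems)) {
    stop(errorCondition(
      paste0("invalid simulation config:\n",
             paste0("  - ", problems, collapse = "\n")),
      class = c("marie_validation_error", "marie_error"),
      violations = problems))
  }
  if (user_targets && length(target_medians) == ncat &&
      any(diff(target_medians) > 0)) {
    warning("target medians do not strictly decrease with patient count; ",
            "the observed size-price trend will not hold everywhere")
  }
  structure(list(seed = as.integer(seed), n_drugs = as.integer(n_drugs),
                 window = parse_window(window),
                 target_medians = stats::setNames(unname(target_medians),
                                                  .category_labels),
                 weights = unname(weights), dispersion = dispersion,
                 exclusion_fractions = ef[c("per_treatment", "per_season",
                                            "not_derivable")],
                 patient_cap = patient_cap),
            class = "simulation_config")
}

# Midpoint of the truncation preimage of an anchor value: any median in
# [a, a+1) / [a, a+10) / [a, a+100) (for <=2 / 3 / >=4 digits) truncates to
# a; the midpoint keeps the floored sample median inside the preimage under
# small noise.
anchor_preimage_midpoint <- function(anchor) {
  digits <- floor(log10(pmax(floor(anchor), 1))) + 1
  width <- ifelse(digits >= 4, 100, ifelse(digits == 3, 10, 1))
  unname(anchor + width / 2)
}

#' Generate a synthetic listing dataset
#'
#' Draws `n_drugs` listing records per the configuration: each record's
#' category is sampled by weight, its patient count uniformly within the
#' category bounds (the unbounded top category is capped at
#' `patient_cap`), and its daily price log-normally around the category's
#' target median. Exclusion flags (per-treatment / per-season basis,
#' price not derivable) are drawn independently with the configured
#' probabilities; non-derivable records carry no daily price. Output is
#' deterministic for a fixed seed.
#'
#' @param config A `simulation_config`.
#' @return Data frame of listing records (columns as in
#'   [filter_listings()]).
#' @export
#' @examples
#' cfg <- simulation_config(seed = 1, n_drugs = 50)
#' head(generate_listings(cfg))
generate_listings <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop_marie("config must be a simulation_config",
               class = "marie_validation_error")
  }
  set.seed(config$seed)
  n <- config$n_drugs
  cats <- patient_categories()
  idx <- sample.int(nrow(cats), n, replace = TRUE, prob = config$weights)
  hi <- pmin(cats$upper[idx] - 1, config$patient_cap)
  lo <- cats$lower[idx]
  max_patients <- lo + floor(stats::runif(n) * (hi - lo + 1))
  max_patients <- pmin(max_patients, hi)
  price <- config$target_medians[idx] *
    exp(stats::rnorm(n, 0, config$dispersion))
  u <- stats::runif(n)
  ef <- config$exclusion_fractions
  basis <- ifelse(u < ef[["per_treatment"]], "per_treatment",
                  ifelse(u < ef[["per_treatment"]] + ef[["per_season"]],
                         "per_season", "per_day"))
  derivable <- stats::runif(n) >= ef[["not_derivable"]]
  data.frame(
    drug_id = sprintf("SYN%05d", seq_len(n)),
    fiscal_year = sample(seq(config$window[1], config$window[2]), n,
                         replace = TRUE),
    daily_price = ifelse(derivable, price, NA_real_),
    max_patients = max_patients,
    price_basis = basis,
    price_derivable = derivable,
    stringsAsFactors = FALSE
  )
}

#' Build a generator configuration that reproduces a given anchor row
#'
#' Returns a `simulation_config` whose per-category target medians sit at
#' the midpoint of each anchor value's truncation preimage, so that (with
#' small dispersion and enough records) the update pipeline's floored,
#' truncated per-category medians equal the given anchor exactly and
#' [update_table()] reproduces [build_table()] of that anchor. Exclusion
#' fractions are zero so every generated record is included.
#'
#' @param anchor Numeric vector of 15 anchor prices (JPY), ordered as
#'   [patient_categories()] or named by category label.
#' @param seed Integer seed for the resulting config.
#' @param n_drugs Records to generate (default 10000, enough to cover all
#'   categories under uniform weights).
#' @param dispersion Log-sd of price noise (default 1e-6, near-degenerate).
#' @param ... Further arguments passed to [simulation_config()].
#' @return A `simulation_config`.
#' @export
invert_anchor_targets <- function(anchor, seed = 1L, n_drugs = 10000L,
                                  dispersion = 1e-6, ...) {
  if (!is.null(names(anchor))) {
    idx <- match_category(names(anchor))
    if (anyNA(idx)) {
      stop_marie("unknown category label(s) in anchor",
                 class = "marie_domain_error")
    }
    anchor <- anchor[order(idx)]
  }
  if (any(truncate_anchor(anchor) != anchor)) {
    stop_marie("anchor values must already be truncated (see ",
               "truncate_anchor())", class = "marie_domain_error")
  }
  suppressWarnings(simulation_config(
    seed = seed, n_drugs = n_drugs,
    target_medians = anchor_preimage_midpoint(anchor),
    dispersion = dispersion,
    exclusion_fractions = c(per_treatment = 0, per_season = 0,
                            not_derivable = 0),
    ...))
}
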