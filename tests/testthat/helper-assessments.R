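# Assessment fixtures built in code.

# All-maximum assessment: 50 base points, 50 additional points.
max_assessment <- function(drug_id = "fixture-max") {
  list(drug_id = drug_id,
       efficacy = "superiority",
       safety = "continued_surveillance",
       scientific_novelty = "novel_mechanism",
       clinical_positioning = "first_option",
       unmet_needs = "low_satisfaction_low_contribution",
       qol = "improved",
       true_endpoints = "improved",
       productivity_loss = "reports_available",
       convenience = "improved",
       diagnosis = "improved",
       pediatric_use = "approved",
       others = list(level = "applicable",
                     justification = "long-term societal benefit"))
}

# All-minimum assessment: 25 base points, 1 additional point (the unmet-needs
# element has no zero level).
min_assessment <- function(drug_id = "fixture-min") {
  list(drug_id = drug_id,
       efficacy = "single_arm",
       safety = "warnings_in_review",
       scientific_novelty = "efficacy_shown",
       clinical_positioning = "one_of_several",
       unmet_needs = "high_satisfaction_high_contribution",
       qol = "not_observed",
       true_endpoints = "not_observed",
       productivity_loss = "no_reports",
       convenience = "none",
       diagnosis = "not_observed",
       pediatric_use = "not_approved",
       others = "not_applicable")
}

modify_assessment <- function(base, ...) {
  changes <- list(...)
  base[names(changes)] <- changes
  base
}

# All level-token combinations for the given elements, as a data frame of
# tokens (one column per element, one row per combination).
level_grid <- function(elements) {
  crit <- marie_criteria()
  do.call(expand.grid, c(
    lapply(elements, function(el) crit$level[crit$element == el]),
    list(stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  )) |> stats::setNames(elements)
}

# Valid all-included listing records hitting the given categories.
listings_for_categories <- function(labels, price = 1000,
                                    fiscal_year = 2020) {
  cats <- patient_categories()
  i <- match(labels, cats$label)
  data.frame(
    drug_id = sprintf("FIX%03d", seq_along(i)),
    fiscal_year = fiscal_year,
    daily_price = price,
    max_patients = cats$lower[i],
    price_basis = "per_day",
    price_derivable = TRUE,
    stringsAsFactors = FALSE
  )
}
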