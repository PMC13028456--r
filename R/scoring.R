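# Scoring criteria for the twelve value elements. Each criterion sentence is
# carried as a description; the short snake-case level token is the
# machine-readable key used in assessment files.

.base_elements <- c("efficacy", "safety", "scientific_novelty",
                    "clinical_positioning")
.additional_elements <- c("unmet_needs", "qol", "true_endpoints",
                          "productivity_loss", "convenience", "diagnosis",
                          "pediatric_use", "others")

.criteria <- rbind(
  data.frame(class = "base", element = "efficacy", rbind(
    c("superiority", 20, "Superiority over active comparator"),
    c("non_inferiority", 15, paste("Non-inferiority over active comparator,",
      "superiority over placebo, or superiority as add-on therapy over",
      "standard of care alone")),
    c("single_arm", 10, "Evaluated in a single-armed trial"))),
  data.frame(class = "base", element = "safety", rbind(
    c("continued_surveillance", 10, paste("Acceptable, with information to be",
      "continuously gathered in post-marketing surveillance")),
    c("warnings_in_review", 5, paste("Acceptable, with issues for warnings or",
      "contraindications discussed in the approval review")))),
  data.frame(class = "base", element = "scientific_novelty", rbind(
    c("novel_mechanism", 10,
      "Efficacy shown or expected, with a novel mechanism of action"),
    c("efficacy_shown", 5, "Efficacy shown or expected to be shown"))),
  data.frame(class = "base", element = "clinical_positioning", rbind(
    c("first_option", 10, "New or first treatment option"),
    c("one_of_several", 5, "One of several treatment options"))),
  data.frame(class = "additional", element = "unmet_needs", rbind(
    c("low_satisfaction_low_contribution", 5,
      "Treatment satisfaction < 50% and drug contribution < 50%"),
    c("low_satisfaction_high_contribution", 3,
      "Treatment satisfaction < 50% and drug contribution > 50%"),
    c("high_satisfaction_low_contribution", 3,
      "Treatment satisfaction > 50% and drug contribution < 50%"),
    c("high_satisfaction_high_contribution", 1,
      "Treatment satisfaction > 50% and drug contribution > 50%"))),
  data.frame(class = "additional", element = "qol", rbind(
    c("improved", 5, paste("QoL improvement from baseline or against placebo",
      "or an active comparator observed")),
    c("not_observed", 0, "Improvement not observed or data not available"))),
  data.frame(class = "additional", element = "true_endpoints", rbind(
    c("improved", 5, "Improvement in true endpoints observed"),
    c("not_observed", 0, "Improvement not observed or data not available"))),
  data.frame(class = "additional", element = "productivity_loss", rbind(
    c("reports_available", 5,
      "Reports available on productivity loss for the indicated disease"),
    c("no_reports", 0,
      "No reports available on productivity loss for the indicated disease"))),
  data.frame(class = "additional", element = "convenience", rbind(
    c("improved", 5, paste("Self-administration possible, administration",
      "interval extended, or administration frequency reduced")),
    c("none", 0, "No convenience improvement"))),
  data.frame(class = "additional", element = "diagnosis", rbind(
    c("improved", 5, "Improvement in diagnosis observed"),
    c("not_observed", 0, "Improvement not observed or data not available"))),
  data.frame(class = "additional", element = "pediatric_use", rbind(
    c("approved", 10, "Approved for use in children"),
    c("not_approved", 0, "Not approved for use in children"))),
  data.frame(class = "additional", element = "others", rbind(
    c("applicable", 10,
      "Other value applicable (free-text justification required)"),
    c("not_applicable", 0, "Not applicable")))
)
names(.criteria)[3:5] <- c("level", "points", "description")
.criteria$points <- as.integer(.criteria$points)

#' Scoring criteria for the twelve value elements
#'
#' The framework scores four base elements (efficacy, safety, scientific
#' novelty, clinical positioning; 50 points maximum, which selects the
#' conversion-table row) and eight additional elements (50 points maximum,
#' which drive the 2-percent-per-point premium). Every criterion has a short
#' snake-case level token used as the key in assessment files; the
#' qualitative criterion text is carried as a description.
#'
#' @return A data frame with columns `class` ("base"/"additional"),
#'   `element`, `level` (token), `points` and `description`.
#' @export
#' @examples
#' subset(marie_criteria(), element == "efficacy")
marie_criteria <- function() .criteria

criteria_for <- function(element) .criteria[.criteria$element == element, ]

points_for <- function(element, level) {
  rows <- .criteria[.criteria$element == element & .criteria$level == level, ]
  if (nrow(rows) != 1) return(NA_integer_)
  rows$points
}

#' Validate a structured value-element assessment
#'
#' Checks a named list (typically parsed from a YAML or JSON assessment
#' file, see [read_assessment()]) against the scoring criteria: every one
#' of the twelve value elements must be present exactly once with a known
#' level token. The "others" element, when scored applicable (10 points),
#' must carry a free-text `justification`, since its criterion is
#' subjective. All violations are reported together, not just the first.
#'
#' @param document Named list: keys are element names, values are level
#'   tokens (or, for elements needing a justification, a list with `level`
#'   and `justification`). An optional `drug_id` entry names the drug.
#' @return A `value_assessment` object.
#' @export
#' @examples
#' a <- validate_assessment(list(
#'   drug_id = "example",
#'   efficacy = "superiority", safety = "continued_surveillance",
#'   scientific_novelty = "novel_mechanism",
#'   clinical_positioning = "first_option",
#'   unmet_needs = "low_satisfaction_low_contribution",
#'   qol = "improved", true_endpoints = "improved",
#'   productivity_loss = "reports_available", convenience = "improved",
#'   diagnosis = "not_observed", pediatric_use = "approved",
#'   others = "not_applicable"))
#' score_base(a)
validate_assessment <- function(document) {
  if (!is.list(document)) {
    stop_marie("assessment must be a named list", class = "marie_validation_error")
  }
  violations <- character(0)
  nm <- names(document)
  if (is.null(nm) || any(nm == "")) {
    stop_marie("assessment entries must all be named",
               class = "marie_validation_error")
  }
  known <- c("drug_id", .base_elements, .additional_elements)
  for (bad in setdiff(nm, known)) {
    violations <- c(violations, paste0("unknown element: '", bad, "'"))
  }
  for (dup in unique(nm[duplicated(nm)])) {
    violations <- c(violations, paste0("duplicate element: '", dup, "'"))
  }
  drug_id <- if ("drug_id" %in% nm) as.character(document$drug_id[[1]]) else ""

  levels <- character(0)
  justification <- NULL
  for (el in c(.base_elements, .additional_elements)) {
    if (!el %in% nm) {
      kind <- if (el %in% .base_elements) "base" else "additional"
      violations <- c(violations,
                      paste0("missing ", kind, " element: '", el, "'"))
      next
    }
    val <- document[[which(nm == el)[1]]]
    just <- NULL
    if (is.list(val)) {
      just <- val$justification
      val <- val$level
    }
    if (is.null(val) || length(val) != 1 || !is.character(val)) {
      violations <- c(violations,
                      paste0("element '", el, "': level must be a single token"))
      next
    }
    if (is.na(points_for(el, val))) {
      violations <- c(violations, paste0(
        "element '", el, "': unknown level '", val, "' (valid: ",
        paste(criteria_for(el)$level, collapse = ", "), ")"))
      next
    }
    if (el == "others" && val == "applicable" &&
        (is.null(just) || !nzchar(trimws(paste(just, collapse = " "))))) {
      violations <- c(violations, paste0(
        "element 'others': level 'applicable' (10 points) requires a ",
        "free-text justification"))
      next
    }
    if (el == "others") justification <- just
    levels[el] <- val
  }
  if (length(violations)) {
    stop(errorCondition(
      paste0("invalid assessment (", length(violations), " violation",
             if (length(violations) > 1) "s" else "", "):\n",
             paste0("  - ", violations, collapse = "\n")),
      class = c("marie_validation_error", "marie_error"),
      violations = violations))
  }
  structure(list(drug_id = drug_id, levels = levels,
                 others_justification = justification),
            class = "value_assessment")
}

as_assessment <- function(x) {
  if (inherits(x, "value_assessment")) x else validate_assessment(x)
}

#' Base points of an assessment
#'
#' Sums the points of the four base elements: efficacy (20/15/10), safety
#' (10/5), scientific novelty (10/5) and clinical positioning (10/5). The
#' total is always a multiple of 5 between 25 and 50 and selects the
#' conversion-table row.
#'
#' @param assessment A `value_assessment` (or a named list, validated
#'   first via [validate_assessment()]).
#' @return Integer base-point total in 25..50.
#' @export
score_base <- function(assessment) {
  a <- as_assessment(assessment)
  sum(vapply(.base_elements,
             function(el) points_for(el, a$levels[[el]]), integer(1)))
}

#' Additional points of an assessment
#'
#' Sums the points of the eight additional elements (unmet needs, QoL, true
#' endpoints, productivity loss, convenience, diagnosis, pediatric use,
#' others). The maximum is 50 points; each point adds a 2% premium to the
#' base daily price (see [apply_premium()]).
#'
#' @inheritParams score_base
#' @return Integer additional-point total in 1..50.
#' @export
score_additional <- function(assessment) {
  a <- as_assessment(assessment)
  sum(vapply(.additional_elements,
             function(el) points_for(el, a$levels[[el]]), integer(1)))
}

#' @export
print.value_assessment <- function(x, ...) {
  cat("Value assessment",
      if (nzchar(x$drug_id)) paste0("for '", x$drug_id, "'"), "\n")
  pts <- vapply(names(x$levels),
                function(el) points_for(el, x$levels[[el]]), integer(1))
  cat(sprintf("  %-22s %-36s %3d\n", names(x$levels), x$levels, pts), sep = "")
  cat("  base points:      ", score_base(x), "\n")
  cat("  additional points:", score_additional(x), "\n")
  invisible(x)
}
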