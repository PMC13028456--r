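# The 15 maximum-patient categories heading the conversion tables, ordered by
# ascending patient count. Intervals are half-open [lower, upper): exactly
# 10,000 patients falls in "10,000 to 30,000", exactly 2,000,000 in
# "More than 2,000,000", so the leading number of each printed label is
# inclusive.
.category_lowers <- c(1, 10, 100, 500, 1000, 3000, 5000, 10000, 30000,
                      50000, 1e5, 3e5, 5e5, 1e6, 2e6)

.category_labels <- c(
  "1 to 10", "10 to 100", "100 to 500", "500 to 1000", "1000 to 3000",
  "3000 to 5000", "5000 to 10,000", "10,000 to 30,000", "30,000 to 50,000",
  "50,000 to 100,000", "100,000 to 300,000", "300,000 to 500,000",
  "500,000 to 1,000,000", "1,000,000 to 2,000,000", "More than 2,000,000")

#' Maximum-patient categories of the conversion table
#'
#' The conversion table bins a drug's projected maximum number of patients
#' into 15 ordered categories, from "1 to 10" (ultra-orphan) up to
#' "More than 2,000,000". Category intervals are half-open from below:
#' a drug with exactly 10,000 patients belongs to "10,000 to 30,000".
#'
#' @return A data frame with one row per category: `label`, `lower`
#'   (inclusive, patients) and `upper` (exclusive; `Inf` for the top
#'   category).
#' @export
#' @examples
#' patient_categories()
patient_categories <- function() {
  data.frame(
    label = .category_labels,
    lower = .category_lowers,
    upper = c(.category_lowers[-1], Inf),
    stringsAsFactors = FALSE
  )
}

#' Assign a maximum-patient count to its conversion-table category
#'
#' @param max_patients Positive whole number(s): the projected maximum
#'   number of patients for the drug.
#' @return Character vector of category labels (see [patient_categories()]).
#' @export
#' @examples
#' assign_patient_category(5)        # "1 to 10"
#' assign_patient_category(10000)    # "10,000 to 30,000"
#' assign_patient_category(2.5e6)    # "More than 2,000,000"
assign_patient_category <- function(max_patients) {
  if (length(max_patients) == 0 || !is.numeric(max_patients) ||
      anyNA(max_patients) || any(!is.finite(max_patients))) {
    stop_marie("max_patients must be a finite positive whole number",
               class = "marie_domain_error")
  }
  if (any(max_patients < 1) || any(max_patients != floor(max_patients))) {
    stop_marie("max_patients must be a whole number >= 1 (got ",
               paste(utils::head(max_patients[max_patients < 1 |
                 max_patients != floor(max_patients)], 3), collapse = ", "),
               ")", class = "marie_domain_error")
  }
  .category_labels[findInterval(max_patients, .category_lowers)]
}

# Canonical form of a category label for matching table headers: lowercase,
# thousands separators and surplus whitespace removed.
normalize_category_label <- function(x) {
  x <- tolower(gsub(",", "", x))
  x <- gsub("\\s+", " ", trimws(x))
  x
}

# Map (possibly reformatted) labels to canonical category indices; NA where
# a label is not recognised.
match_category <- function(labels) {
  match(normalize_category_label(labels),
        normalize_category_label(.category_labels))
}

stop_marie <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "marie_error")))
}
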