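#' Apply the additional-point premium to a base daily price
#'
#' Each additional point adds a fixed premium fraction (2% by default) of
#' the base daily price, so 5 additional points raise the price by 10% and
#' the 50-point maximum exactly doubles it. The premium is linear, not
#' compounding, mirroring the usefulness/marketability/pediatric premiums
#' of the Japanese pricing system.
#'
#' @param base_price Positive base daily price, JPY.
#' @param additional_points Integer in 0..50.
#' @param premium_rate Premium fraction per additional point (default 0.02).
#' @return Final daily price, JPY (unrounded).
#' @export
#' @examples
#' apply_premium(1000, 5)    # 1100
#' apply_premium(141100, 50) # 282200
apply_premium <- function(base_price, additional_points, premium_rate = 0.02) {
  if (!is.numeric(base_price) || anyNA(base_price) || any(base_price <= 0)) {
    stop_marie("base_price must be positive", class = "marie_domain_error")
  }
  if (!is.numeric(additional_points) || anyNA(additional_points) ||
      any(additional_points < 0) || any(additional_points > 50) ||
      any(additional_points != floor(additional_points))) {
    stop_marie("additional_points must be a whole number in [0, 50]",
               class = "marie_domain_error")
  }
  if (!is.numeric(premium_rate) || length(premium_rate) != 1 ||
      premium_rate <= 0) {
    stop_marie("premium_rate must be a positive fraction per point",
               class = "marie_domain_error")
  }
  base_price * (1 + premium_rate * additional_points)
}

#' Price a drug from its value assessment and maximum patient count
#'
#' Composes the whole pricing pipeline: score the base elements, look the
#' base daily price up in the conversion table at the drug's
#' maximum-patient category, score the additional elements, and apply the
#' per-point premium. The returned quote keeps the unrounded final price;
#' a display value rounded half-up to 0.01 JPY is carried alongside.
#'
#' @param assessment A `value_assessment` (or named list; see
#'   [validate_assessment()]).
#' @param max_patients Projected maximum number of patients (positive whole
#'   number).
#' @param table A `conversion_table`.
#' @param premium_rate Premium fraction per additional point (default 0.02).
#' @return A `price_quote` object with fields `drug_id`, `base_points`,
#'   `additional_points`, `category`, `base_price`, `premium_rate`,
#'   `premium_factor`, `final_price`, `final_price_rounded`.
#' @export
price_drug <- function(assessment, max_patients, table, premium_rate = 0.02) {
  a <- as_assessment(assessment)
  base_points <- score_base(a)
  additional_points <- score_additional(a)
  category <- assign_patient_category(max_patients)
  base_price <- lookup_base_price(table, base_points, category)
  final <- apply_premium(base_price, additional_points, premium_rate)
  structure(list(
    drug_id = a$drug_id,
    base_points = base_points,
    additional_points = additional_points,
    max_patients = max_patients,
    category = category,
    base_price = base_price,
    premium_rate = premium_rate,
    premium_factor = 1 + premium_rate * additional_points,
    final_price = final,
    final_price_rounded = floor(final * 100 + 0.5) / 100
  ), class = "price_quote")
}

#' @export
print.price_quote <- function(x, ...) {
  cat("Price quote", if (nzchar(x$drug_id)) paste0("for '", x$drug_id, "'"),
      "\n")
  cat(sprintf("  base points:        %d\n", x$base_points))
  cat(sprintf("  additional points:  %d\n", x$additional_points))
  cat(sprintf("  patient category:   %s (max %s patients)\n", x$category,
              formatC(x$max_patients, format = "d", big.mark = ",")))
  cat(sprintf("  base daily price:   %s JPY\n",
              formatC(x$base_price, format = "d", big.mark = ",")))
  cat(sprintf("  premium factor:     %.2f (%.0f%% per point)\n",
              x$premium_factor, 100 * x$premium_rate))
  cat(sprintf("  final daily price:  %s JPY\n",
              formatC(x$final_price_rounded, format = "f", digits = 2,
                      big.mark = ",")))
  invisible(x)
}
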