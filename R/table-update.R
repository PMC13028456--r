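# Rebuilding the conversion table from drug-listing data: filter listings to
# per-day, price-derivable records in the fiscal-year window, take the
# per-category median daily listing price, truncate each median into an
# anchor, and expand the anchor row into a full table.

.listing_columns <- c("drug_id", "fiscal_year", "daily_price", "max_patients",
                      "price_basis", "price_derivable")
.price_bases <- c("per_day", "per_treatment", "per_season")

#' Parse a fiscal-year window
#'
#' Accepts `"FY2015:FY2024"` (or `"2015:2024"`) or an integer vector of two
#' fiscal years. Japanese fiscal years run April to March of the following
#' calendar year; see [fiscal_year()].
#'
#' @param window Window specification.
#' @return Integer vector `c(from, to)`.
#' @export
parse_window <- function(window) {
  if (is.character(window) && length(window) == 1) {
    parts <- strsplit(window, ":", fixed = TRUE)[[1]]
    window <- suppressWarnings(as.integer(gsub("^[Ff][Yy]", "", parts)))
  }
  window <- as.integer(window)
  if (length(window) != 2 || anyNA(window) || window[1] > window[2]) {
    stop_marie("window must be 'FY<from>:FY<to>' or c(from, to) with ",
               "from <= to", class = "marie_domain_error")
  }
  window
}

#' Fiscal year of a calendar date
#'
#' The Japanese fiscal year runs from April to March of the following
#' calendar year: a drug listed on 2025-02-01 belongs to FY2024.
#'
#' @param date A `Date` (or something coercible to one).
#' @return Integer fiscal year(s).
#' @export
#' @examples
#' fiscal_year(as.Date("2025-02-01")) # 2024
#' fiscal_year(as.Date("2025-04-01")) # 2025
fiscal_year <- function(date) {
  date <- as.Date(date)
  y <- as.integer(format(date, "%Y"))
  m <- as.integer(format(date, "%m"))
  y - as.integer(m < 4)
}

#' Filter listing records for table construction
#'
#' Keeps records inside the fiscal-year window whose price is quoted per
#' day and is stated or derivable; everything else goes to the exclusion
#' log with a single reason each. Drugs priced per treatment course or per
#' season are rejected because the table's unit is a daily price. The
#' included set and the log always partition the input.
#'
#' @param records Data frame of listing records with columns `drug_id`,
#'   `fiscal_year`, `daily_price`, `max_patients`, `price_basis`
#'   (`per_day`/`per_treatment`/`per_season`), `price_derivable` (logical).
#' @param window Fiscal-year window (see [parse_window()]).
#' @return List with `included` (data frame) and `exclusions` (data frame
#'   of `drug_id`, `reason`).
#' @export
filter_listings <- function(records, window) {
  records <- validate_listings(records)
  window <- parse_window(window)
  reason <- rep(NA_character_, nrow(records))
  out_of_window <- records$fiscal_year < window[1] |
    records$fiscal_year > window[2]
  reason[out_of_window] <- "outside_window"
  pick <- function(cond, label) {
    sel <- is.na(reason) & cond
    reason[sel] <<- label
  }
  pick(records$price_basis == "per_treatment", "per_treatment_basis")
  pick(records$price_basis == "per_season", "per_season_basis")
  pick(!records$price_derivable | is.na(records$daily_price),
       "price_not_stated_or_derivable")
  list(
    included = records[is.na(reason), , drop = FALSE],
    exclusions = data.frame(drug_id = records$drug_id[!is.na(reason)],
                            reason = reason[!is.na(reason)],
                            stringsAsFactors = FALSE)
  )
}

validate_listings <- function(records) {
  if (!is.data.frame(records)) {
    stop_marie("records must be a data frame", class = "marie_parse_error")
  }
  missing <- setdiff(.listing_columns, names(records))
  if (length(missing)) {
    stop_marie("listing records missing column(s): ",
               paste(missing, collapse = ", "), class = "marie_parse_error")
  }
  bad_basis <- which(!records$price_basis %in% .price_bases)
  if (length(bad_basis)) {
    stop_marie("invalid price_basis in record(s) ",
               paste(utils::head(bad_basis, 5), collapse = ", "),
               " (valid: ", paste(.price_bases, collapse = ", "), ")",
               class = "marie_parse_error")
  }
  bad_pat <- which(is.na(records$max_patients) | records$max_patients < 1)
  if (length(bad_pat)) {
    stop_marie("max_patients missing or < 1 in record(s) ",
               paste(utils::head(bad_pat, 5), collapse = ", "),
               class = "marie_parse_error")
  }
  bad_price <- which(!is.na(records$daily_price) & records$daily_price <= 0)
  if (length(bad_price)) {
    stop_marie("non-positive daily_price in record(s) ",
               paste(utils::head(bad_price, 5), collapse = ", "),
               class = "marie_parse_error")
  }
  records
}

#' Median daily listing price per patient category
#'
#' Records are binned by [assign_patient_category()] and the median daily
#' price is taken per category. With an even record count, the median is
#' the mean of the two central values; the result is floored to integer
#' JPY so downstream truncation operates on a whole number. Empty
#' categories are reported with `n = 0` and `median = NA`, never silently
#' filled.
#'
#' @param included Data frame of filtered listing records (see
#'   [filter_listings()]).
#' @return Data frame with one row per category: `category`, `n`,
#'   `median_price`.
#' @export
compute_category_medians <- function(included) {
  included <- validate_listings(included)
  cat_labels <- assign_patient_category(included$max_patients)
  out <- data.frame(category = .category_labels,
                    n = 0L, median_price = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(.category_labels)) {
    prices <- included$daily_price[cat_labels == .category_labels[i]]
    out$n[i] <- length(prices)
    if (length(prices)) out$median_price[i] <- floor(stats::median(prices))
  }
  out
}

#' Rebuild the conversion table from listing data
#'
#' Full update pipeline: [filter_listings()] then
#' [compute_category_medians()], [truncate_anchor()] per category, and
#' [build_table()]. Every one of the 15 categories must contain at least
#' one included record — a partial anchor row is not meaningful, so an
#' empty category is an error naming the categories concerned.
#'
#' @inheritParams filter_listings
#' @param provenance Text recording the window, e.g. `"FY2015-FY2024"`.
#' @return List with `table` (the new `conversion_table`), `exclusions`
#'   (the exclusion log) and `summary` (per-category `n`, `median_price`
#'   and `anchor`).
#' @export
update_table <- function(records, window, provenance = NULL) {
  window <- parse_window(window)
  if (is.null(provenance)) {
    provenance <- sprintf("FY%d-FY%d", window[1], window[2])
  }
  flt <- filter_listings(records, window)
  med <- compute_category_medians(flt$included)
  if (any(med$n == 0)) {
    stop_marie("cannot build table: no included listings in category(s) ",
               paste(sQuote(med$category[med$n == 0], q = FALSE),
                     collapse = ", "),
               class = "marie_domain_error")
  }
  med$anchor <- truncate_anchor(med$median_price)
  list(table = build_table(stats::setNames(med$anchor, med$category),
                           provenance = provenance),
       exclusions = flt$exclusions,
       summary = med)
}

#' Compare two conversion tables by their anchor rows
#'
#' Reports, per patient category, the percent change of the 35-point
#' anchor between an old and a new table, both exactly and rounded to the
#' nearest multiple of 10% (the one-significant-figure trend statements of
#' the framework: e.g. "increased by approximately 50%" for ultra-orphan
#' drugs between the FY2012-2021 and FY2015-2024 tables).
#'
#' @param old,new `conversion_table` objects over the same category scheme.
#' @return Data frame with `category`, `old_anchor`, `new_anchor`,
#'   `pct_change`, `pct_change_rounded`.
#' @export
#' @examples
#' cmp <- compare_tables(marie_table2(), marie_table3())
#' cmp[cmp$category == "1 to 10", ]
compare_tables <- function(old, new) {
  stopifnot(inherits(old, "conversion_table"),
            inherits(new, "conversion_table"))
  if (!identical(names(old$anchor), names(new$anchor))) {
    stop_marie("tables use different category schemes",
               class = "marie_domain_error")
  }
  pct <- 100 * (new$anchor - old$anchor) / old$anchor
  data.frame(
    category = names(old$anchor),
    old_anchor = unname(old$anchor),
    new_anchor = unname(new$anchor),
    pct_change = unname(pct),
    pct_change_rounded = unname(sign(pct) * floor(abs(pct) / 10 + 0.5) * 10),
    stringsAsFactors = FALSE
  )
}
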