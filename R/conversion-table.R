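# The conversion table maps (base points, maximum-patient category) to a
# base daily price in JPY. It carries no information beyond its anchor row:
# every cell is the 35-point anchor price moved by 10% of the anchor per
# 5-point step, i.e. cell(p, c) = anchor(c) * (1 + 0.10 * (p - 35) / 5).
# Anchors divisible by 10 make every cell an exact integer, which is what
# keeps reproduction of the published tables bit-exact.

.points_range <- seq(5L, 50L, by = 5L)

#' Truncate a median daily price into a conversion-table anchor
#'
#' Fractions of the per-category median listing price are dropped before it
#' becomes the 35-point anchor: a 3-digit median loses its last digit
#' (floored to a multiple of 10) and a median of 4 or more digits loses its
#' last two digits (floored to a multiple of 100). Medians of 1 or 2 digits
#' are kept as is; fractional medians are floored to an integer first, and
#' the digit count is taken on that floored integer.
#'
#' @param median_price Positive number(s): per-category median daily listing
#'   price, JPY.
#' @return Truncated integer price(s), JPY. Idempotent and never larger
#'   than the input.
#' @export
#' @examples
#' truncate_anchor(455)      # 450
#' truncate_anchor(141187)   # 141100
#' truncate_anchor(84)       # 84
truncate_anchor <- function(median_price) {
  if (!is.numeric(median_price) || length(median_price) == 0 ||
      anyNA(median_price) || any(median_price <= 0)) {
    stop_marie("median_price must be positive", class = "marie_domain_error")
  }
  m <- floor(median_price)
  digits <- floor(log10(pmax(m, 1))) + 1
  out <- m
  out[digits == 3] <- m[digits == 3] - m[digits == 3] %% 10
  out[digits >= 4] <- m[digits >= 4] - m[digits >= 4] %% 100
  out
}

#' Build a conversion table from its 35-point anchor row
#'
#' Expands an anchor row (one truncated median daily price per
#' maximum-patient category) into the full 10 x 15 grid of base daily
#' prices for base points 5, 10, ..., 50: each 5-point step up adds 10% of
#' the anchor price, each step down removes 10%. Anchors divisible by 10
#' (as all published anchors are) give exact integer cells; otherwise cells
#' are rounded half-up to integer JPY with a warning.
#'
#' @param anchor Numeric vector of 15 positive anchor prices (JPY), ordered
#'   as [patient_categories()] (ascending patient count), or named by
#'   category label.
#' @param provenance Text recording the fiscal-year window the anchors were
#'   estimated from, e.g. `"FY2015-FY2024"`.
#' @param anchor_points Base-point value the anchor row corresponds to
#'   (default 35, the published convention).
#' @param step_rate Price change per 5-point step as a fraction of the
#'   anchor (default 0.10).
#' @return A `conversion_table` object.
#' @export
#' @examples
#' tab <- build_table(marie_table3()$anchor, provenance = "FY2015-FY2024")
#' lookup_base_price(tab, 50, "More than 2,000,000")  # 104
build_table <- function(anchor, provenance = "", anchor_points = 35L,
                        step_rate = 0.10) {
  if (!is.numeric(anchor) || length(anchor) != nrow(patient_categories())) {
    stop_marie("anchor must be a numeric vector with one price per ",
               "patient category (", nrow(patient_categories()), ")",
               class = "marie_domain_error")
  }
  if (anyNA(anchor) || any(anchor <= 0)) {
    stop_marie("anchor prices must all be positive",
               class = "marie_domain_error")
  }
  if (!is.null(names(anchor))) {
    idx <- match_category(names(anchor))
    if (anyNA(idx)) {
      stop_marie("unknown category label(s) in anchor: ",
                 paste(names(anchor)[is.na(idx)], collapse = ", "),
                 class = "marie_domain_error")
    }
    anchor <- anchor[order(idx)]
  }
  anchor <- unname(anchor)
  if (!anchor_points %in% .points_range) {
    stop_marie("anchor_points must be one of ",
               paste(.points_range, collapse = ", "),
               class = "marie_domain_error")
  }
  steps <- (.points_range - anchor_points) / 5
  increment <- anchor * step_rate
  if (all(increment == floor(increment))) {
    # exact integer arithmetic: the per-step increment is integral
    grid <- outer(steps, increment) + rep(anchor, each = length(steps))
  } else {
    warning("anchor not divisible by 10: cells rounded half-up to integer JPY")
    grid <- floor(outer(1 + step_rate * steps, anchor) + 0.5)
  }
  dimnames(grid) <- list(as.character(.points_range), .category_labels)
  structure(list(anchor = stats::setNames(anchor, .category_labels),
                 grid = grid, provenance = provenance,
                 anchor_points = as.integer(anchor_points),
                 step_rate = step_rate),
            class = "conversion_table")
}

new_table_from_grid <- function(grid, provenance = "", anchor_points = 35L,
                                step_rate = 0.10) {
  structure(list(
    anchor = stats::setNames(grid[as.character(anchor_points), ],
                             .category_labels),
    grid = grid, provenance = provenance,
    anchor_points = as.integer(anchor_points), step_rate = step_rate),
    class = "conversion_table")
}

#' Look up the base daily price for given base points and category
#'
#' @param table A `conversion_table`.
#' @param base_points Base-point total; must be a multiple of 5 in 5..50
#'   (no interpolation is defined between rows).
#' @param category Category label (see [patient_categories()]).
#' @return Base daily price, JPY.
#' @export
lookup_base_price <- function(table, base_points, category) {
  stopifnot(inherits(table, "conversion_table"))
  if (length(base_points) != 1 || !is.numeric(base_points) ||
      !base_points %in% .points_range) {
    stop_marie("base_points must be a multiple of 5 in [5, 50]; got ",
               paste(base_points, collapse = ","),
               class = "marie_domain_error")
  }
  idx <- match_category(category)
  if (length(idx) != 1 || is.na(idx)) {
    stop_marie("unknown patient category: '", category, "'",
               class = "marie_domain_error")
  }
  unname(table$grid[as.character(base_points), idx])
}

#' Audit a conversion-table grid against its anchor row
#'
#' Recomputes every cell from the table's anchor row by the
#' 10%-per-5-points rule and reports any cell that disagrees. An empty
#' report certifies that the grid carries no information beyond its anchor.
#'
#' @param table A `conversion_table` (e.g. one read from a file with
#'   [read_table()], whose grid is kept exactly as printed).
#' @return Data frame of mismatching cells (`base_points`, `category`,
#'   `expected`, `found`); zero rows when the grid is consistent.
#' @export
verify_table <- function(table) {
  stopifnot(inherits(table, "conversion_table"))
  expected <- suppressWarnings(
    build_table(table$anchor, table$provenance, table$anchor_points,
                table$step_rate))$grid
  bad <- which(expected != table$grid, arr.ind = TRUE)
  data.frame(
    base_points = as.integer(rownames(table$grid)[bad[, 1]]),
    category = colnames(table$grid)[bad[, 2]],
    expected = expected[bad],
    found = table$grid[bad],
    stringsAsFactors = FALSE
  )
}

#' @export
print.conversion_table <- function(x, ...) {
  cat("Conversion table (base daily price, JPY)",
      if (nzchar(x$provenance)) paste0("[", x$provenance, "]"), "\n")
  cat("  anchor row:", x$anchor_points, "points; step:",
      sprintf("%+.0f%% of anchor per 5 points\n", 100 * x$step_rate))
  disp <- apply(x$grid[rev(seq_len(nrow(x$grid))), rev(seq_len(ncol(x$grid)))],
                c(1, 2), function(v) formatC(v, format = "d", big.mark = ","))
  print(disp, quote = FALSE, right = TRUE)
  invisible(x)
}
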