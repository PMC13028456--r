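# Delimited-text readers and writers. Conversion tables travel as CSV (a
# base_points column plus one column per category label, thousands
# separators allowed) with a JSON sidecar carrying provenance and the
# anchor row; listings and comparisons are plain CSV; assessments are YAML
# or JSON documents.

parse_price <- function(x, what, where) {
  out <- suppressWarnings(as.numeric(gsub(",", "", trimws(x))))
  bad <- which(!is.na(x) & nzchar(trimws(x)) & is.na(out))
  if (length(bad)) {
    stop_marie("non-numeric ", what, " at ", where, " ",
               paste(utils::head(bad, 5), collapse = ", "),
               class = "marie_parse_error")
  }
  out
}

#' Read a conversion table from CSV (+ JSON sidecar)
#'
#' The CSV must contain a `base_points` column and one column per patient
#' category, in any order; cells may carry thousands separators (e.g.
#' `"141,100"`). The grid is kept exactly as read, so [verify_table()] can
#' audit a transcribed table against its anchor row. Provenance is taken
#' from a JSON sidecar (same path with `.json` extension) when present.
#'
#' @param path CSV file path.
#' @param sidecar Optional explicit path to the JSON sidecar.
#' @return A `conversion_table`.
#' @export
read_table <- function(path, sidecar = NULL) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         strip.white = TRUE)
  if (!"base_points" %in% names(raw)) {
    stop_marie("malformed table header in ", path,
               ": no 'base_points' column", class = "marie_parse_error")
  }
  cat_cols <- setdiff(names(raw), "base_points")
  idx <- match_category(cat_cols)
  if (anyNA(idx)) {
    stop_marie("malformed table header in ", path, ": unknown category ",
               "column(s) ", paste(cat_cols[is.na(idx)], collapse = ", "),
               class = "marie_parse_error")
  }
  if (length(cat_cols) != length(.category_labels)) {
    stop_marie("malformed table in ", path, ": expected ",
               length(.category_labels), " category columns, found ",
               length(cat_cols), class = "marie_parse_error")
  }
  pts <- parse_price(raw$base_points, "base_points", "row")
  if (nrow(raw) != length(.points_range) ||
      !setequal(pts, .points_range)) {
    stop_marie("malformed table in ", path, ": expected one row per base ",
               "points value ", paste(range(.points_range), collapse = "-"),
               class = "marie_parse_error")
  }
  grid <- matrix(NA_real_, length(.points_range), length(.category_labels),
                 dimnames = list(as.character(.points_range),
                                 .category_labels))
  for (j in seq_along(cat_cols)) {
    grid[as.character(pts), idx[j]] <-
      parse_price(raw[[cat_cols[j]]], paste0("price in '", cat_cols[j], "'"),
                  "row")
  }
  provenance <- ""
  anchor_points <- 35L
  if (is.null(sidecar)) {
    candidate <- paste0(tools::file_path_sans_ext(path), ".json")
    if (file.exists(candidate)) sidecar <- candidate
  }
  if (!is.null(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$provenance)) provenance <- meta$provenance
    if (!is.null(meta$anchor_points)) {
      anchor_points <- as.integer(meta$anchor_points)
    }
  }
  new_table_from_grid(grid, provenance = provenance,
                      anchor_points = anchor_points)
}

#' Write a conversion table to CSV (+ JSON sidecar)
#'
#' Writes the grid in display order (base points descending, patient
#' categories from largest population to smallest, matching the published
#' layout) with thousands separators, plus a JSON sidecar holding
#' provenance, anchor points and the anchor row. `read_table()` of the
#' written pair restores the table exactly.
#'
#' @param table A `conversion_table`.
#' @param path Output CSV path; the sidecar goes to the same path with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  stopifnot(inherits(table, "conversion_table"))
  disp <- table$grid[rev(seq_len(nrow(table$grid))),
                     rev(seq_len(ncol(table$grid))), drop = FALSE]
  out <- data.frame(base_points = rownames(disp), check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(disp))) {
    out[[colnames(disp)[j]]] <- formatC(disp[, j], format = "d",
                                        big.mark = ",")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  jsonlite::write_json(
    list(provenance = table$provenance,
         anchor_points = table$anchor_points,
         anchor = as.list(table$anchor)),
    paste0(tools::file_path_sans_ext(path), ".json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a listings CSV
#'
#' Expects header `drug_id, fiscal_year, daily_price, max_patients,
#' price_basis, price_derivable`; prices and patient counts may carry
#' thousands separators; `daily_price` may be empty (price not stated).
#' Parse errors name the offending data line.
#'
#' @param path CSV file path.
#' @return Data frame of listing records.
#' @export
read_listings <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         strip.white = TRUE)
  missing <- setdiff(.listing_columns, names(raw))
  if (length(missing)) {
    stop_marie("malformed listings header in ", path, ": missing ",
               paste(missing, collapse = ", "), class = "marie_parse_error")
  }
  records <- data.frame(
    drug_id = raw$drug_id,
    fiscal_year = as.integer(parse_price(raw$fiscal_year, "fiscal_year",
                                         "data line")),
    daily_price = parse_price(raw$daily_price, "daily_price", "data line"),
    max_patients = parse_price(raw$max_patients, "max_patients", "data line"),
    price_basis = trimws(raw$price_basis),
    price_derivable = parse_flag(raw$price_derivable, path),
    stringsAsFactors = FALSE
  )
  validate_listings(records)
}

parse_flag <- function(x, path) {
  val <- c("true" = TRUE, "1" = TRUE, "yes" = TRUE,
           "false" = FALSE, "0" = FALSE, "no" = FALSE)[tolower(trimws(x))]
  if (anyNA(val)) {
    stop_marie("invalid price_derivable flag in ", path, " at data line ",
               paste(utils::head(which(is.na(val)), 5), collapse = ", "),
               class = "marie_parse_error")
  }
  unname(val)
}

#' Write listings to CSV
#'
#' @param records Data frame of listing records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_listings <- function(records, path) {
  records <- validate_listings(records)
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read a value assessment from a YAML or JSON file
#'
#' One drug per file; keys are element names, values are level tokens (the
#' "others" element may be a mapping with `level` and `justification`).
#' The format is chosen by extension (`.yaml`/`.yml` vs `.json`).
#'
#' @param path Assessment file path.
#' @return A validated `value_assessment`.
#' @export
read_assessment <- function(path) {
  ext <- tolower(tools::file_ext(path))
  doc <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = FALSE),
    stop_marie("unsupported assessment format '.", ext,
               "' (use .yaml/.yml or .json)", class = "marie_parse_error"))
  doc <- lapply(doc, function(v) if (is.list(v)) v else as.character(v))
  validate_assessment(doc)
}

bundled_table <- function(name) {
  read_table(system.file("extdata", paste0(name, ".csv"), package = "marie",
                         mustWork = TRUE))
}

#' Bundled conversion tables
#'
#' The two published conversion tables ship with the package as CSV
#' fixtures: `marie_table2()` is the FY2012-FY2021 table and
#' `marie_table3()` the updated FY2015-FY2024 table. Both grids are stored
#' exactly as printed and pass [verify_table()] against their anchor rows.
#'
#' @return A `conversion_table`.
#' @export
marie_table2 <- function() bundled_table("conversion_table_fy2012_fy2021")

#' @rdname marie_table2
#' @export
marie_table3 <- function() bundled_table("conversion_table_fy2015_fy2024")
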