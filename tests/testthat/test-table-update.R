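test_that("filtering excludes by basis, derivability and window", {
  recs <- listings_for_categories(patient_categories()$label)
  recs$price_basis[1] <- "per_treatment"
  recs$price_basis[2] <- "per_season"
  recs$price_derivable[3] <- FALSE
  recs$daily_price[3] <- NA
  recs$daily_price[4] <- NA  # stated as derivable but no price given
  recs$fiscal_year[5] <- 2011

  flt <- filter_listings(recs, "FY2015:FY2024")
  expect_identical(nrow(flt$included) + nrow(flt$exclusions), nrow(recs))
  reasons <- stats::setNames(flt$exclusions$reason, flt$exclusions$drug_id)
  expect_identical(unname(reasons[recs$drug_id[1]]), "per_treatment_basis")
  expect_identical(unname(reasons[recs$drug_id[2]]), "per_season_basis")
  expect_identical(unname(reasons[recs$drug_id[3]]),
                   "price_not_stated_or_derivable")
  expect_identical(unname(reasons[recs$drug_id[4]]),
                   "price_not_stated_or_derivable")
  expect_identical(unname(reasons[recs$drug_id[5]]), "outside_window")
})

test_that("an all-valid batch passes the filter untouched", {
  recs <- listings_for_categories(patient_categories()$label)
  recs$fiscal_year <- rep(2015:2024, length.out = nrow(recs))
  flt <- filter_listings(recs, c(2015, 2024))
  expect_identical(nrow(flt$included), nrow(recs))
  expect_identical(nrow(flt$exclusions), 0L)
})

test_that("included and excluded records always partition the input", {
  set.seed(23)
  for (i in 1:5) {
    cfg <- simulation_config(seed = i, n_drugs = 200)
    recs <- generate_listings(cfg)
    flt <- filter_listings(recs, cfg$window)
    expect_identical(nrow(flt$included) + nrow(flt$exclusions), nrow(recs))
    expect_setequal(c(flt$included$drug_id, flt$exclusions$drug_id),
                    recs$drug_id)
  }
})

test_that("category medians floor the midpoint of even-sized samples", {
  recs <- listings_for_categories(rep("1 to 10", 3))
  recs$daily_price <- c(100, 200, 300)
  med <- compute_category_medians(recs)
  expect_identical(med$median_price[med$category == "1 to 10"], 200)

  recs2 <- listings_for_categories(rep("10 to 100", 2))
  recs2$daily_price <- c(100, 201)
  med2 <- compute_category_medians(recs2)
  expect_identical(med2$median_price[med2$category == "10 to 100"], 150)

  recs3 <- listings_for_categories("100 to 500")
  recs3$daily_price <- 92513
  med3 <- compute_category_medians(recs3)
  expect_identical(med3$median_price[med3$category == "100 to 500"], 92513)

  # empty categories flagged, never filled
  expect_identical(med3$n[med3$category == "1 to 10"], 0L)
  expect_true(is.na(med3$median_price[med3$category == "1 to 10"]))
})

test_that("the update pipeline reproduces a table from inverted targets", {
  t3 <- marie_table3()
  cfg <- invert_anchor_targets(t3$anchor, seed = 42, n_drugs = 10000)
  res <- update_table(generate_listings(cfg), cfg$window)
  expect_identical(res$table$grid, t3$grid)
  expect_identical(res$table$anchor, t3$anchor)
  expect_identical(nrow(res$exclusions), 0L)
  expect_identical(sum(res$summary$n), 10000L)
})

test_that("update_table is invariant to record order and to excluded noise", {
  cfg <- invert_anchor_targets(marie_table3()$anchor, seed = 9,
                               n_drugs = 2000)
  recs <- generate_listings(cfg)
  res <- update_table(recs, cfg$window)

  set.seed(1)
  shuffled <- recs[sample(nrow(recs)), ]
  expect_identical(update_table(shuffled, cfg$window)$table$grid,
                   res$table$grid)

  noisy <- rbind(recs, data.frame(
    drug_id = "NOISE", fiscal_year = 2020, daily_price = 1e9,
    max_patients = 5, price_basis = "per_treatment",
    price_derivable = TRUE, stringsAsFactors = FALSE))
  res_noisy <- update_table(noisy, cfg$window)
  expect_identical(res_noisy$table$grid, res$table$grid)
  expect_identical(nrow(res_noisy$exclusions), 1L)
  expect_identical(res_noisy$exclusions$reason, "per_treatment_basis")
})

test_that("an empty category aborts the update naming the category", {
  labels <- setdiff(patient_categories()$label, "1 to 10")
  recs <- listings_for_categories(labels)
  err <- expect_error(update_table(recs, c(2015, 2024)),
                      class = "marie_domain_error")
  expect_match(conditionMessage(err), "1 to 10", fixed = TRUE)
})

test_that("table comparison reports the published anchor trends", {
  cmp <- compare_tables(marie_table2(), marie_table3())
  row_orphan <- cmp[cmp$category == "1 to 10", ]
  expect_equal(row_orphan$pct_change, 100 * (141100 - 92500) / 92500)
  expect_identical(row_orphan$pct_change_rounded, 50)
  row_mid <- cmp[cmp$category == "3000 to 5000", ]
  expect_equal(row_mid$pct_change, 100 * (8500 - 10800) / 10800)
  expect_identical(row_mid$pct_change_rounded, -20)
})

test_that("a table compared with itself (or its rebuild) changes by zero", {
  t3 <- marie_table3()
  expect_identical(compare_tables(t3, t3)$pct_change, rep(0, 15))
  rebuilt <- build_table(t3$anchor, t3$provenance)
  expect_identical(compare_tables(t3, rebuilt)$pct_change, rep(0, 15))
})

test_that("fiscal years follow the April-to-March convention", {
  expect_identical(fiscal_year(as.Date("2025-02-01")), 2024L)
  expect_identical(fiscal_year(as.Date("2025-03-31")), 2024L)
  expect_identical(fiscal_year(as.Date("2025-04-01")), 2025L)
  expect_identical(parse_window("FY2015:FY2024"), c(2015L, 2024L))
  expect_error(parse_window("FY2024:FY2015"), class = "marie_domain_error")
})
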