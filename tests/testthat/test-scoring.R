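test_that("base and additional points match the published worked cases", {
  a <- validate_assessment(max_assessment())
  expect_identical(score_base(a), 50L)
  expect_identical(score_additional(a), 50L)

  expect_identical(score_base(min_assessment()), 25L)  # 10 + 5 + 5 + 5

  non_inf <- modify_assessment(max_assessment(), efficacy = "non_inferiority")
  expect_identical(score_base(non_inf), 45L)  # 15 + 10 + 10 + 10

  # unmet needs alone at its 5-point criterion, everything else at bottom
  unmet_only <- modify_assessment(
    min_assessment(), unmet_needs = "low_satisfaction_low_contribution")
  expect_identical(score_additional(unmet_only), 5L)
})

test_that("both 3-point unmet-needs situations score equally but stay distinct", {
  crit <- subset(marie_criteria(), element == "unmet_needs" & points == 3)
  expect_identical(nrow(crit), 2L)
  expect_identical(unique(crit$points), 3L)
  a <- modify_assessment(min_assessment(),
                         unmet_needs = "low_satisfaction_high_contribution")
  b <- modify_assessment(min_assessment(),
                         unmet_needs = "high_satisfaction_low_contribution")
  expect_identical(score_additional(a), score_additional(b))
})

test_that("exhaustive enumeration bounds the base total", {
  grid <- level_grid(c("efficacy", "safety", "scientific_novelty",
                       "clinical_positioning"))
  expect_identical(nrow(grid), 24L)  # 3 x 2 x 2 x 2
  totals <- vapply(seq_len(nrow(grid)), function(i) {
    doc <- modify_assessment(
      max_assessment(),
      efficacy = grid$efficacy[i], safety = grid$safety[i],
      scientific_novelty = grid$scientific_novelty[i],
      clinical_positioning = grid$clinical_positioning[i])
    score_base(doc)
  }, integer(1))
  expect_true(all(totals >= 25 & totals <= 50))
  expect_true(all(totals %% 5 == 0))
  expect_identical(max(totals), 50L)
  expect_identical(min(totals), 25L)
  expect_setequal(unique(totals), seq(25L, 50L, 5L))
})

test_that("exhaustive enumeration bounds the additional total at 50", {
  elements <- c("unmet_needs", "qol", "true_endpoints", "productivity_loss",
                "convenience", "diagnosis", "pediatric_use", "others")
  grid <- level_grid(elements)
  expect_identical(nrow(grid), 512L)  # 4 x 2^7 token combinations
  totals <- vapply(seq_len(nrow(grid)), function(i) {
    doc <- min_assessment()
    for (el in elements) {
      doc[[el]] <- if (el == "others" && grid[i, el] == "applicable") {
        list(level = "applicable", justification = "enumerated case")
      } else {
        grid[i, el]
      }
    }
    score_additional(doc)
  }, integer(1))
  expect_identical(max(totals), 50L)
  expect_identical(min(totals), 1L)  # unmet needs has no zero level
  expect_true(all(totals <= 50))
})

test_that("scores are invariant under element reordering", {
  doc <- max_assessment()
  for (i in 1:5) {
    shuffled <- doc[sample(names(doc))]
    expect_identical(score_base(shuffled), score_base(doc))
    expect_identical(score_additional(shuffled), score_additional(doc))
  }
})

test_that("validation reports every violation and names missing elements", {
  doc <- max_assessment()
  doc$safety <- NULL
  err <- expect_error(validate_assessment(doc), class = "marie_validation_error")
  expect_match(conditionMessage(err), "safety")

  broken <- modify_assessment(max_assessment(), efficacy = "miracle",
                              qol = "excellent")
  broken$safety <- NULL
  err <- expect_error(validate_assessment(broken),
                      class = "marie_validation_error")
  expect_length(err$violations, 3)
  expect_match(conditionMessage(err), "efficacy")
  expect_match(conditionMessage(err), "qol")
  expect_match(conditionMessage(err), "safety")

  unknown <- max_assessment()
  unknown$price <- "high"
  expect_error(validate_assessment(unknown), "unknown element",
               class = "marie_validation_error")
})

test_that("'others' at 10 points demands a written justification", {
  bare <- modify_assessment(max_assessment(), others = "applicable")
  expect_error(validate_assessment(bare), "justification",
               class = "marie_validation_error")
  justified <- modify_assessment(
    max_assessment(),
    others = list(level = "applicable", justification = "first in class"))
  expect_identical(score_additional(justified), 50L)
})
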