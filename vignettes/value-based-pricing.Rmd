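---
title: "Qualitative value-based drug pricing with marie"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Qualitative value-based drug pricing with marie}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marie)
```

## The pricing model

`marie` implements a multiple-criteria qualitative value-based pricing
(VBP) framework for newly listed drugs. Unlike cost-effectiveness-based
VBP, it requires neither a comparator drug nor a health-economic model:
twelve value elements are scored qualitatively from public information
(review reports, trial publications), and the scores are monetized through
a conversion table calibrated on daily prices of drugs actually listed on
Japan's National Health Insurance (NHI) price list.

The price of a drug is built in three steps:

1. **Base points** (25–50). Four base elements are each assigned exactly
   one criterion level: efficacy (20/15/10 points), safety (10/5),
   scientific novelty (10/5) and clinical positioning (10/5). The levels
   are qualitative sentences (e.g. efficacy 20 = superiority over an
   active comparator; 10 = evaluated in a single-armed trial); the full
   vocabulary is in `marie_criteria()`.

2. **Base daily price.** The base-point total and the drug's projected
   maximum number of patients select a cell of the *conversion table*: a
   10 × 15 grid of base daily prices (JPY) over base points 5, 10, …, 50
   and 15 ordered patient categories from "1 to 10" (ultra-orphan) to
   "More than 2,000,000". The table is fully determined by its 35-point
   *anchor row*: the per-category median daily listing price over a
   10-year fiscal window, with fractions truncated (3-digit medians are
   floored to a multiple of 10, medians of 4+ digits to a multiple of
   100), extrapolated at ±10% of the anchor per 5-point step:

   $$\mathrm{cell}(p, c) = \mathrm{anchor}(c)\,
     \Bigl(1 + 0.10\,\frac{p - 35}{5}\Bigr).$$

3. **Additional-point premium.** Eight additional elements (unmet needs,
   QoL, true endpoints, productivity loss, convenience, diagnosis,
   pediatric use, others; at most 50 points in total) add a linear 2%
   premium per point: 5 points raise the base price by 10%, and the
   50-point maximum exactly doubles it. The premium is deliberately
   linear, not compounding — the framework's own worked example (5 points
   → exactly +10%) forces that form.

Two calibrations of the table ship with the package: `marie_table2()`
(FY2012–FY2021) and `marie_table3()` (FY2015–FY2024), both stored exactly
as published and audited at test time by `verify_table()`, which recomputes
all 150 cells from the anchor row.

```{r}
a <- read_assessment(system.file("extdata", "example_assessment.yaml",
                                 package = "marie"))
price_drug(a, max_patients = 5, table = marie_table3())
```

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `premium_rate` | 0.02 / point | premium fraction per additional point |
| `anchor_points` | 35 | base-point row holding the median prices |
| `step_rate` | 0.10 / 5 points | extrapolation slope, as a fraction of the anchor |
| points range | 5–50, step 5 | rows of the table; no interpolation between rows |

The defaults reproduce the published tables. They are parameters rather
than constants because the framework is explicitly meant to be
re-calibrated — to another country's listing data, another premium
schedule — without changing its structure. Why the *median* listing price
maps to the 35-point row in particular is a convention of the original
calibration; `build_table()` therefore takes `anchor_points` as an
argument rather than hard-coding 35.

## Scoring conventions

Criterion sentences are unusable as machine keys, so every level carries a
short snake-case token (`superiority`, `continued_surveillance`, …);
assessment files (YAML or JSON, one drug per file) map element names to
tokens. Three conventions are worth stating:

* The two clinically distinct 3-point unmet-needs situations
  (satisfaction < 50% with contribution > 50%, and the converse) keep
  separate tokens with equal points, preserving the audit trail.
* "Others" scored 10 has no objective criterion, so the package refuses it
  without a free-text `justification`.
* The criteria define no zero level for unmet needs (the weakest is
  1 point) and no safety level below 5, and the package adds none: the
  additional total of a fully assessed drug is therefore at least 1, and
  the base total at least 25. `apply_premium()` still accepts
  `additional_points = 0` directly, which is the zero-premium identity.

## Rebuilding the table from listing data

`update_table()` re-runs the calibration on a listings dataset (CSV; one
record per newly listed drug with its daily price at listing, maximum
patient count, fiscal year and price-basis flags):

1. `filter_listings()` keeps records inside the fiscal-year window whose
   price is quoted per day and stated or derivable. Drugs priced per
   treatment course or per season are excluded — the table's unit is a
   daily price. Every input record lands in exactly one of
   included/excluded; a record failing several rules is logged once, with
   the first applicable reason in the order window, per-treatment,
   per-season, price-not-derivable.
2. `compute_category_medians()` bins included records by
   `assign_patient_category()` and takes per-category medians. Category
   intervals are half-open from below, so a count equal to a printed
   boundary (10,000; 2,000,000) belongs to the higher category — the
   convention that makes each label's leading number inclusive. An
   even-sized category's median (mean of the central pair) is floored to
   integer JPY so the truncation rule operates on a whole number; the
   digit count for truncation is taken on that floored integer.
3. `truncate_anchor()` and `build_table()` turn the medians into a table.
   A category with no included record aborts the update naming the
   category: a partial anchor row is not meaningful. Filtering happens
   before category assignment, but the result is order-independent either
   way.

`compare_tables()` reports per-category anchor changes both exactly and
rounded to the nearest multiple of 10%, which is how the framework's
one-significant-figure trend statements are operationalized. Between the
two bundled calibrations the ultra-orphan ("1 to 10") anchor rises by
52.5% → "approximately +50%", and the "3000 to 5000" anchor falls by
21.3% → "approximately −20%". The published narrative treats
"3000 to 10,000" as one trend; the table has no such bin, so the report
keeps the two categories separate (both round to −20%).

```{r}
cmp <- compare_tables(marie_table2(), marie_table3())
cmp[cmp$category %in% c("1 to 10", "3000 to 5000"), ]
```

## The synthetic listings generator

The calibration source (council listing materials) is not machine-readable,
so `generate_listings()` emulates its statistical shape for testing:
372 records over FY2015–FY2024 by default, each drawn by sampling a patient
category, a patient count uniform within the category's bounds (the
unbounded top category is capped at 10,000,000 for sampling), and a daily
price log-normal around the category's target median. Log-normal noise is
the natural choice for a quantity spanning 32 to 183,430 JPY/day across
categories; the default log-sd of 0.6 gives roughly twofold interquartile
spread within a category, a plausible desk-scale stand-in. Exclusion flags
are drawn independently (defaults: 0.5% per-treatment, 0.3% per-season, 7%
not price-derivable, about 8% exclusions overall, in line with the
published exclusion counts). Category weights default to uniform because
the published extraction reports no per-category counts.

`invert_anchor_targets()` builds the end-to-end test fixture: given an
anchor row it returns a generator configuration whose target medians sit
at the *midpoint* of each anchor's truncation preimage (450 → 455,
141,100 → 141,150, 80 → 80.5). The midpoint matters: a target placed
exactly on the anchor would, under any nonzero noise, let the sample
median fall a hair below it about half the time, and the floor would then
truncate to the next bin down. With midpoints, near-degenerate dispersion
(10⁻⁶) and 10,000 records, the full pipeline reproduces the FY2015–FY2024
table bit-exactly — the round-trip the acceptance suite checks.

What the generator does **not** emulate: temporal price trends inside the
window, drug-class structure, correlation between patient count and
exclusion probability, and the real (unknown) per-category record counts.
A passing round-trip therefore certifies the *pipeline arithmetic* —
filtering, medians, truncation, extrapolation — not the epidemiology of
real listings; the target medians are strictly an input. Accordingly the
generator warns (rather than errors) when user-supplied target medians do
not decrease monotonically with patient count: the observed trend holds
broadly, but the published anchor rows themselves contain local reversals
(FY2015–24: 51,200 for "10 to 100" vs 53,900 for "100 to 500"), so strict
monotonicity cannot be a validity requirement.

## Numerical choices

* All published anchors are divisible by 10, so every cell of a rebuilt
  table is computed with exact integer arithmetic (anchor plus a whole
  number of anchor/10 steps) — reproduction of the printed grids is
  bit-exact, with no decimal-rounding layer needed. A user-supplied anchor
  not divisible by 10 still yields a defined table: cells are rounded
  half-up to integer JPY with a warning.
* Quotes keep the unrounded final price; a display value rounded half-up
  to 0.01 JPY travels alongside, since NHI list prices can carry fractions
  of a yen and no final rounding rule is part of the framework.
* `truncate_anchor()` is idempotent and never increases its input; medians
  of 1–2 digits are left unchanged because the truncation rule only
  addresses 3 and 4+ digits.
* Base points outside the 5–50 lattice are an error, not an interpolation:
  the table is defined only on its printed rows.

## Problem sizes

The test suite enumerates all 24 base-element and 512 additional-element
level combinations exhaustively, audits all 300 cells of the two bundled
tables, and runs the synthetic round-trip at 10,000 records; everything
completes in a few seconds on one CPU.

## Limitations

Scoring a real drug still requires human judgment on regulatory documents;
the package validates and prices assessments, it does not produce them.
The bundled tables inherit the published calibration's choices (10-year
window, median, 35-point anchor row) and, as the calibration data are not
deposited, the original 364/372-drug extractions cannot be reproduced
here — the update pipeline is instead validated on synthetic listings with
known ground truth. Per-treatment and per-season priced drugs are outside
the framework's unit of account, and no currency conversion or inflation
adjustment is attempted.
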