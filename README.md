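# marie — multiple-criteria qualitative value-based drug pricing

`marie` prices new drugs by the value they deliver rather than by their
production cost, using a qualitative multiple-criteria scheme that needs
neither a comparator drug nor a health-economic model. It is aimed at
pharmacoeconomists and pricing analysts studying value-based alternatives
to cost-plus pricing under Japan's National Health Insurance (NHI) system,
where new drugs are listed within 60–90 days of approval and pricing
methods must stay fast and transparent.

## The model

Twelve value elements are scored from public information against fixed
qualitative criteria (`marie_criteria()`):

* **Base elements** — efficacy (20/15/10 points), safety (10/5),
  scientific novelty (10/5), clinical positioning (10/5); the total
  (25–50) selects the row of a *conversion table*.
* **Conversion table** — a 10 × 15 grid of base daily prices (JPY) over
  base points `p = 5, 10, …, 50` and 15 maximum-patient categories from
  "1 to 10" to "More than 2,000,000". The grid is generated entirely from
  its 35-point *anchor row* — the truncated per-category median daily
  price of drugs listed over a 10-year fiscal window:

  ```
  cell(p, c) = anchor(c) × (1 + 0.10 × (p − 35) / 5)
  ```

* **Additional elements** — unmet needs, QoL, true endpoints, productivity
  loss, convenience, diagnosis, pediatric use, others (max 50 points);
  each point adds a **2% premium** to the base price, so 5 points → +10%
  and 50 points exactly double it.

Both published calibrations ship with the package: `marie_table2()`
(FY2012–FY2021) and `marie_table3()` (FY2015–FY2024). The package also
rebuilds tables from listing data (`update_table()`), compares calibrations
(`compare_tables()`), and generates synthetic listing datasets
(`generate_listings()`) so the whole update pipeline is testable without
any external data.

## Worked example

Score and price a hypothetical ultra-orphan drug (5 patients) whose
assessment ships with the package:

```r
library(marie)
a <- read_assessment(system.file("extdata", "example_assessment.yaml",
                                 package = "marie"))
price_drug(a, max_patients = 5, table = marie_table3())
#> Price quote for 'example-ultra-orphan'
#>   base points:        50
#>   additional points:  25
#>   patient category:   1 to 10 (max 5 patients)
#>   base daily price:   183,430 JPY
#>   premium factor:     1.50 (2% per point)
#>   final daily price:  275,145.00 JPY
```

All four base elements sit at their top criterion (20 + 10 + 10 + 10 = 50
base points), so the drug reads the 50-point row of the FY2015–FY2024
table in the "1 to 10" category: 183,430 JPY/day. Its 25 additional
points add a 50% premium (2% × 25), giving 275,145 JPY per patient per
day.

Comparing the two calibrations reproduces the published trends — the
ultra-orphan anchor rose by about 50% while the 3000–5000-patient anchor
fell by about 20%:

```r
cmp <- compare_tables(marie_table2(), marie_table3())
cmp[cmp$category %in% c("1 to 10", "3000 to 5000"), ]
#>      category old_anchor new_anchor pct_change pct_change_rounded
#>       1 to 10      92500     141100   52.54054                 50
#>  3000 to 5000      10800       8500  -21.29630                -20
```

A command-line wrapper is installed at
`system.file("cli", "marie", package = "marie")` with subcommands `score`,
`price`, `build-table`, `verify-table`, `update-table`, `compare-tables`
and `simulate`.

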