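Package: hdbindex
Title: Healthy Diet Basket Adequacy of National Food Supplies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess how closely national and regional food supplies
    align with the Healthy Diet Basket (HDB), the six-food-group reference
    diet used by UN agencies for global diet monitoring. Reads food balance
    sheet style commodity panels (old- and new-era FAOSTAT dialects), maps
    commodities to HDB food groups, computes the Healthy Diet Basket Index
    (HDBI) of supply adequacy with a WHO free-sugar share check, summarizes
    country scores by region and decade with confidence intervals, and
    projects HDBI under scenario percentage-change trajectories applied to a
    base-year supply. Includes a synthetic food-balance-sheet generator with
    ground truth so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
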