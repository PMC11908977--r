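# Shared fixtures and independent oracles for the suite.

# Small noise-free panel used across modules.
tiny_config <- function(sigma = 0, seed = 42, ...) {
  sim_config(n_regions = 2, countries_per_region = 3, years = 2000:2015,
             sigma = sigma, seed = seed, ...)
}

# Independent brute-force evaluation of the adequacy index: loop over the
# six groups, accumulate the proportional deficit only where supply is
# below target, subtract the mean. Deliberately written without reusing any
# package internals.
hdbi_oracle <- function(q, targets) {
  total <- 0
  for (g in names(targets)) {
    qi <- if (g %in% names(q)) q[[g]] else 0
    if (qi < targets[[g]]) total <- total + (targets[[g]] - qi) / targets[[g]]
  }
  1 - total / length(targets)
}

# Random six-group supply vectors spanning zero, sub-target, and excess.
random_supply_vector <- function(targets) {
  setNames(runif(6, 0, 3 * targets), names(targets))
}

write_lines_tmp <- function(lines, name = "fixture.csv") {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  writeLines(lines, path)
  path
}

# One-commodity-per-group supply file in the new-era dialect, plus the
# matching single-letter mapping, for desk-sized end-to-end cases.
desk_fixture_files <- function(dir, rows) {
  sup <- file.path(dir, "supply_new.csv")
  header <- "Area Code (ISO3),Area,Item Code,Item,Element Code,Element,Year,Unit,Value"
  body <- sprintf('%s,%s,%s,%s,664,Food supply (kcal/capita/day),%d,kcal/capita/day,%g',
                  rows$country, rows$country, rows$code, rows$code,
                  rows$year, rows$kcal)
  writeLines(c(header, body), sup)
  old <- file.path(dir, "supply_old.csv")
  writeLines("Country Code,Country,Item Code,Item,Element Code,Element,Year,Unit,Value",
             old)
  map <- file.path(dir, "mapping.csv")
  writeLines(c("commodity_code,commodity_name,display_aggregate,group",
               "STA,staples,staples,starchy_staples",
               "FRU,fruits,fruits,fruits",
               "VEG,vegetables,vegetables,vegetables",
               "ASF,animal foods,animal foods,animal_source_foods",
               "LEG,legumes,legumes,legumes_nuts_seeds",
               "OIL,oils,oils,oils_fats",
               "SUG,sugar,sugar,SUGAR",
               "SPI,spices,spices,EXCLUDED"), map)
  list(supply_old = old, supply_new = sup, mapping = map)
}
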