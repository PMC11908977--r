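test_that("a single supply row round-trips with the era tag applied", {
  path <- write_lines_tmp(c(
    "Country Code,Country,Item Code,Item,Element Code,Element,Year,Unit,Value",
    "IND,India,2511,Wheat and products,664,Food supply (kcal/capita/day),1961,kcal/capita/day,500"
  ))
  tab <- read_supply_table(path, era = "old")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$country_code, "IND")
  expect_equal(tab$year, 1961L)
  expect_equal(tab$commodity_code, "2511")
  expect_identical(tab$kcal, 500)
  expect_equal(tab$era, "old")
})

test_that("non-energy element rows are dropped with a logged count", {
  path <- write_lines_tmp(c(
    "Area Code (ISO3),Area,Item Code,Item,Element Code,Element,Year,Unit,Value",
    "KEN,Kenya,2511,Wheat and products,664,Food supply (kcal/capita/day),2015,kcal/capita/day,400",
    "KEN,Kenya,2511,Wheat and products,674,Protein supply quantity (g/capita/day),2015,g/capita/day,12"
  ))
  expect_message(tab <- read_supply_table(path, era = "new"), "dropped 1 row")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$kcal, 400)
})

test_that("a header-only file yields an empty table with a warning", {
  path <- write_lines_tmp(
    "Country Code,Country,Item Code,Item,Element Code,Element,Year,Unit,Value")
  expect_warning(tab <- read_supply_table(path, era = "old"), "no data rows")
  expect_equal(nrow(tab), 0)
  expect_named(tab, c("country_code", "year", "commodity_code",
                      "commodity_name", "kcal", "era"))
})

test_that("invalid rows fail hard with informative errors", {
  neg <- write_lines_tmp(c(
    "Country Code,Country,Item Code,Item,Element Code,Element,Year,Unit,Value",
    "IND,India,2511,Wheat,664,Food supply (kcal/capita/day),1961,kcal/capita/day,-5"
  ), "neg.csv")
  expect_error(read_supply_table(neg, era = "old"), "negative kcal.*row 1")

  bad_year <- write_lines_tmp(c(
    "Country Code,Country,Item Code,Item,Element Code,Element,Year,Unit,Value",
    "IND,India,2511,Wheat,664,Food supply (kcal/capita/day),MCMXCI,kcal/capita/day,5"
  ), "year.csv")
  expect_error(read_supply_table(bad_year, era = "old"), "unparseable year")

  no_col <- write_lines_tmp(c(
    "Country Code,Country,Item Code,Item,Element Code,Element,Year,Unit",
    "IND,India,2511,Wheat,664,Food supply (kcal/capita/day),1961,kcal/capita/day"
  ), "nocol.csv")
  expect_error(read_supply_table(no_col, era = "old"), "missing required column: Value")

  dup <- write_lines_tmp(c(
    "Country Code,Country,Item Code,Item,Element Code,Element,Year,Unit,Value",
    "IND,India,2511,Wheat,664,Food supply (kcal/capita/day),1961,kcal/capita/day,5",
    "IND,India,2511,Wheat,664,Food supply (kcal/capita/day),1961,kcal/capita/day,7"
  ), "dup.csv")
  expect_error(read_supply_table(dup, era = "old"), "duplicate")
})

make_records <- function(country, years, kcal, era) {
  tibble::tibble(country_code = country, year = as.integer(years),
                 commodity_code = "2511", commodity_name = "Wheat",
                 kcal = kcal, era = era)
}

test_that("merge_eras splits eras at the cutover without touching values", {
  old <- make_records("AAA", 1961:2009, 100, "old")
  new <- make_records("AAA", 2010:2022, 200, "new")
  merged <- merge_eras(old, new)
  expect_equal(sort(unique(merged$year)), 1961:2022)
  expect_equal(nrow(merged), nrow(old) + nrow(new))
  expect_true(all(merged$era[merged$year < 2010] == "old"))
  expect_true(all(merged$era[merged$year >= 2010] == "new"))
})

test_that("overlap rows from the losing era are dropped and counted", {
  old <- make_records("AAA", 2005:2013, 100, "old")
  new <- make_records("AAA", 2010:2013, 200, "new")
  # brute-force expectation for the overlap
  expected_dropped <- sum(old$year >= 2010)
  expect_message(merged <- merge_eras(old, new),
                 sprintf("dropped %d old-era", expected_dropped))
  expect_equal(nrow(merged),
               sum(old$year < 2010) + sum(new$year >= 2010))
  # new era wins throughout the overlap, values untouched
  expect_true(all(merged$kcal[merged$year >= 2010] == 200))
})

test_that("a country present only in the new era enters at its first new-era year", {
  old <- make_records("AAA", 1961:2009, 100, "old")
  new <- rbind(make_records("AAA", 2010:2022, 200, "new"),
               make_records("SSD", 2012:2022, 150, "new"))
  merged <- merge_eras(old, new)
  ssd <- merged[merged$country_code == "SSD", ]
  expect_equal(min(ssd$year), 2012)
})

test_that("merging two empty tables is an error", {
  empty <- make_records(character(), integer(), double(), character())
  expect_error(merge_eras(empty, empty), "empty")
})

test_that("population tables are validated", {
  ok <- write_lines_tmp(c("country_code,year,population",
                          "AAA,2010,1e6", "BBB,2010,3e6"))
  tab <- read_population(ok)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$population, c(1e6, 3e6))

  dup <- write_lines_tmp(c("country_code,year,population",
                           "AAA,2010,1e6", "AAA,2010,2e6"), "dup.csv")
  expect_error(read_population(dup), "duplicate")

  zero <- write_lines_tmp(c("country_code,year,population", "AAA,2010,0"),
                          "zero.csv")
  expect_error(read_population(zero), "positive")
})

test_that("region schemes validate against the configured region list", {
  ok <- write_lines_tmp(c("country_code,subregion,region",
                          "IND,Southern Asia,South Asia",
                          "KEN,Eastern Africa,Sub-Saharan Africa"))
  scheme <- read_region_scheme(ok)
  expect_equal(region_lookup(scheme, "IND"), "South Asia")
  expect_equal(attr(scheme, "regions"), hdb_regions())

  expect_warning(r <- region_lookup(scheme, c("IND", "ZZZ")), "ZZZ")
  expect_equal(r, c("South Asia", NA))

  two <- write_lines_tmp(c("country_code,subregion,region",
                           "IND,Southern Asia,South Asia",
                           "IND,Eastern Africa,Sub-Saharan Africa"), "two.csv")
  expect_error(read_region_scheme(two), "more than one")

  bad <- write_lines_tmp(c("country_code,subregion,region",
                           "IND,Southern Asia,Middle Earth"), "bad.csv")
  expect_error(read_region_scheme(bad), "Middle Earth")
})

test_that("country-code aliases normalize to one key space", {
  path <- write_lines_tmp(c(
    "Country Code,Country,Item Code,Item,Element Code,Element,Year,Unit,Value",
    "SUN,USSR,2511,Wheat,664,Food supply (kcal/capita/day),1985,kcal/capita/day,900"
  ))
  tab <- read_supply_table(path, era = "old", aliases = c(SUN = "RUS"))
  expect_equal(tab$country_code, "RUS")
})

test_that("writing then reading a simulated panel is field-for-field identical", {
  sim <- simulate_fbs(tiny_config())
  dir <- withr::local_tempdir()
  paths <- write_fbs_fixture(sim, dir)
  old <- read_supply_table(paths$supply_old, era = "old")
  new <- read_supply_table(paths$supply_new, era = "new")
  merged <- merge_eras(old, new)
  expect_equal(as.data.frame(merged), as.data.frame(sim$records))
  # kcal values are bit-identical through the round trip
  expect_identical(merged$kcal, sim$records$kcal)
  pop <- read_population(paths$population)
  expect_equal(as.data.frame(pop), as.data.frame(sim$populations))
})
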