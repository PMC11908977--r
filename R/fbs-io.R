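#' Default column maps for food-balance-sheet export dialects
#'
#' Old-era (historic, data through 2013 under the former balancing
#' methodology) and new-era (2010 onward) exports label the same content
#' differently: the historic files carry `Country Code`/`Country`, the new
#' files `Area Code (ISO3)`/`Area`. The map translates file column names to
#' the internal field names `country_code`, `commodity_code`,
#' `commodity_name`, `year`, `kcal`, and the optional `element` used to keep
#' only daily per-capita dietary-energy rows.
#'
#' @param era `"old"` or `"new"`.
#' @return Named list: internal field name -> column name in the file.
#' @export
fbs_col_map <- function(era = c("old", "new")) {
  era <- match.arg(era)
  base <- list(
    commodity_code = "Item Code",
    commodity_name = "Item",
    year           = "Year",
    kcal           = "Value",
    element        = "Element"
  )
  if (era == "old") {
    c(list(country_code = "Country Code"), base)
  } else {
    c(list(country_code = "Area Code (ISO3)"), base)
  }
}

# Uppercase/trim country codes and apply an alias table (named vector,
# file code -> canonical ISO3) for historical entities.
normalize_country_codes <- function(codes, aliases = NULL) {
  codes <- toupper(trimws(as.character(codes)))
  if (!is.null(aliases) && length(aliases)) {
    names(aliases) <- toupper(trimws(names(aliases)))
    hit <- codes %in% names(aliases)
    codes[hit] <- unname(aliases[codes[hit]])
  }
  codes
}

#' Read a food-balance-sheet supply table
#'
#' Reads a delimited commodity panel of daily per-capita food supply in
#' kilocalories, validates it, and tags each record with its era. When the
#' file carries an element column, only rows whose element describes daily
#' per-capita dietary energy (matching `kcal_element`) are kept; the number
#' dropped is logged to the message stream. Kilocalorie values pass through
#' unaltered.
#'
#' @param path Path to a CSV file.
#' @param era `"old"` or `"new"`; selects the default column dialect and is
#'   recorded on every row.
#' @param col_map Named list mapping internal field names to file column
#'   names; see [fbs_col_map()]. `country_code`, `commodity_code`, `year` and
#'   `kcal` are required in the file; `commodity_name` and `element` are used
#'   when present.
#' @param aliases Optional named character vector renaming historical or
#'   non-standard country codes to canonical ISO3 codes.
#' @param kcal_element Regular expression identifying the dietary-energy
#'   element rows; rows with a non-matching element are dropped.
#' @return Tibble of records with columns `country_code`, `year`,
#'   `commodity_code`, `commodity_name`, `kcal`, `era`.
#' @export
read_supply_table <- function(path, era = c("old", "new"),
                              col_map = fbs_col_map(era), aliases = NULL,
                              kcal_element = "kcal/capita/day") {
  era <- match.arg(era)
  if (!file.exists(path)) abort(paste0("supply file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  required <- c("country_code", "commodity_code", "year", "kcal")
  for (field in required) {
    col <- col_map[[field]]
    if (is.null(col)) abort(paste0("col_map does not define required field: ", field))
    if (!col %in% names(raw)) {
      abort(paste0("supply file ", path, " is missing required column: ", col))
    }
  }
  if (nrow(raw) == 0) {
    warn(paste0("supply file has a header but no data rows: ", path))
    return(tibble(country_code = character(), year = integer(),
                  commodity_code = character(), commodity_name = character(),
                  kcal = double(), era = character()))
  }
  el_col <- col_map[["element"]]
  if (!is.null(el_col) && el_col %in% names(raw)) {
    keep <- grepl(kcal_element, raw[[el_col]])
    if (any(!keep)) {
      inform(sprintf("dropped %d row(s) whose element is not per-capita dietary energy",
                     sum(!keep)))
    }
    raw <- raw[keep, , drop = FALSE]
  }
  year <- suppressWarnings(as.integer(raw[[col_map$year]]))
  bad <- which(is.na(year))
  if (length(bad)) {
    abort(sprintf("unparseable year at data row %d: '%s'",
                  bad[1], raw[[col_map$year]][bad[1]]))
  }
  if (any(year < 1961 | year > 2100)) {
    abort(sprintf("year out of supported range [1961, 2100] at data row %d",
                  which(year < 1961 | year > 2100)[1]))
  }
  kcal <- suppressWarnings(as.numeric(raw[[col_map$kcal]]))
  bad <- which(is.na(kcal))
  if (length(bad)) {
    abort(sprintf("unparseable kcal value at data row %d: '%s'",
                  bad[1], raw[[col_map$kcal]][bad[1]]))
  }
  bad <- which(kcal < 0)
  if (length(bad)) {
    abort(sprintf("negative kcal (%g) at data row %d", kcal[bad[1]], bad[1]))
  }
  name_col <- col_map[["commodity_name"]]
  records <- tibble(
    country_code = normalize_country_codes(raw[[col_map$country_code]], aliases),
    year = year,
    commodity_code = as.character(raw[[col_map$commodity_code]]),
    commodity_name = if (!is.null(name_col) && name_col %in% names(raw)) {
      as.character(raw[[name_col]])
    } else {
      as.character(raw[[col_map$commodity_code]])
    },
    kcal = kcal,
    era = era
  )
  dup <- duplicated(records[c("country_code", "year", "commodity_code")])
  if (any(dup)) {
    d <- records[which(dup)[1], ]
    abort(sprintf("duplicate (country, year, commodity) key: (%s, %d, %s)",
                  d$country_code, d$year, d$commodity_code))
  }
  records
}

#' Merge old- and new-era supply tables at a fixed cutover year
#'
#' The balancing methodology behind food balance sheets changed in 2010,
#' which leaves a level discontinuity between the two data eras. No splicing
#' or level adjustment is performed: years before `cutover_year` are taken
#' from the old-era table and years at or after it from the new-era table,
#' exactly as published. Rows from the losing era in the overlap are dropped
#' and counted.
#'
#' @param old_table,new_table Validated record tables from
#'   [read_supply_table()].
#' @param cutover_year First year served by the new era. Default 2010.
#' @return Tibble of records spanning both eras, with the `era` label
#'   preserved on every row.
#' @export
merge_eras <- function(old_table, new_table, cutover_year = 2010) {
  if (nrow(old_table) == 0 && nrow(new_table) == 0) {
    abort("both supply tables are empty; nothing to merge")
  }
  for (tab in list(old = old_table, new = new_table)) {
    dup <- duplicated(tab[c("country_code", "year", "commodity_code")])
    if (any(dup)) abort("duplicate (country, year, commodity) key within one era")
  }
  old_keep <- old_table$year < cutover_year
  new_keep <- new_table$year >= cutover_year
  dropped_old <- sum(!old_keep)
  dropped_new <- sum(!new_keep)
  if (dropped_old > 0) {
    inform(sprintf("dropped %d old-era row(s) at/after the %d cutover",
                   dropped_old, cutover_year))
  }
  if (dropped_new > 0) {
    inform(sprintf("dropped %d new-era row(s) before the %d cutover",
                   dropped_new, cutover_year))
  }
  bind_rows(old_table[old_keep, , drop = FALSE],
            new_table[new_keep, , drop = FALSE]) |>
    arrange(.data$country_code, .data$year, .data$commodity_code)
}

#' Read a population table
#'
#' @param path CSV with columns `country_code`, `year`, `population`
#'   (persons), one row per country-year.
#' @param aliases Optional country-code alias table, as in
#'   [read_supply_table()].
#' @return Validated tibble.
#' @export
read_population <- function(path, aliases = NULL) {
  if (!file.exists(path)) abort(paste0("population file not found: ", path))
  tab <- readr::read_csv(path, show_col_types = FALSE)
  miss <- setdiff(c("country_code", "year", "population"), names(tab))
  if (length(miss)) {
    abort(paste0("population file is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  out <- tibble(
    country_code = normalize_country_codes(tab$country_code, aliases),
    year = as.integer(tab$year),
    population = as.numeric(tab$population)
  )
  if (any(is.na(out$population)) || any(out$population <= 0)) {
    abort("population must be positive for every row")
  }
  if (anyDuplicated(out[c("country_code", "year")])) {
    abort("duplicate (country, year) in population table")
  }
  out
}

#' Read a country-to-region scheme
#'
#' Maps each country to one subregion and one world region. The region list
#' is configuration: any scheme whose region names fall within `regions`
#' validates, with the bundled default being the seven-region scheme of
#' [hdb_regions()].
#'
#' @param path CSV with columns `country_code`, `subregion`, `region`.
#' @param regions Character vector of allowed region names.
#' @param aliases Optional country-code alias table.
#' @return Tibble with one row per country and a `regions` attribute holding
#'   the configured region list.
#' @export
read_region_scheme <- function(path, regions = hdb_regions(), aliases = NULL) {
  if (!file.exists(path)) abort(paste0("region scheme file not found: ", path))
  tab <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  miss <- setdiff(c("country_code", "subregion", "region"), names(tab))
  if (length(miss)) {
    abort(paste0("region scheme is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  out <- tibble(
    country_code = normalize_country_codes(tab$country_code, aliases),
    subregion = tab$subregion,
    region = tab$region
  ) |> distinct()
  if (anyDuplicated(out$country_code)) {
    dup <- out$country_code[duplicated(out$country_code)][1]
    abort(paste0("country mapped to more than one subregion/region: ", dup))
  }
  unknown <- setdiff(unique(out$region), regions)
  if (length(unknown)) {
    abort(paste0("region name(s) not in the configured region list: ",
                 paste(unknown, collapse = ", ")))
  }
  attr(out, "regions") <- regions
  out
}

#' Look up the region of one or more countries
#'
#' Countries absent from the scheme return `NA` with a warning so callers can
#' exclude them downstream.
#'
#' @param scheme Tibble from [read_region_scheme()].
#' @param country_codes Character vector of country codes.
#' @param level `"region"` or `"subregion"`.
#' @return Character vector parallel to `country_codes`.
#' @export
region_lookup <- function(scheme, country_codes, level = c("region", "subregion")) {
  level <- match.arg(level)
  idx <- match(country_codes, scheme$country_code)
  if (anyNA(idx)) {
    warn(paste0("country code(s) not in region scheme: ",
                paste(unique(country_codes[is.na(idx)]), collapse = ", ")))
  }
  scheme[[level]][idx]
}
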