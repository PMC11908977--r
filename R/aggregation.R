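#' Default decade definitions
#'
#' Interior decades run the full ten years; the opening decade starts at the
#' first food-balance-sheet year (1961) and the closing one covers whatever
#' part of the 2020s the data reach (by default 2020--2022).
#'
#' @param last_year Final data year included in the 2020s. Default 2022.
#' @return Tibble with columns `label`, `start`, `end`.
#' @export
hdb_decades <- function(last_year = 2022) {
  tibble(
    label = c("1960s", "1970s", "1980s", "1990s", "2000s", "2010s", "2020s"),
    start = c(1961L, 1970L, 1980L, 1990L, 2000L, 2010L, 2020L),
    end   = c(1969L, 1979L, 1989L, 1999L, 2009L, 2019L, as.integer(last_year))
  )
}

# Columns of a food-group supply table that aggregate as per-capita energy.
supply_value_cols <- function(supplies) {
  intersect(c(hdb_groups(), "sugar_kcal", "excluded_kcal", "total_kcal"),
            names(supplies))
}

# Population-weighted per-capita mean of every supply column within the
# grouping given by `by` (a character vector per country-row, e.g. region).
weighted_supply <- function(supplies, by) {
  cols <- supply_value_cols(supplies)
  supplies$...by <- by
  supplies |>
    group_by(entity = .data$...by, year = .data$year) |>
    summarise(
      across(all_of(cols), ~ weighted.mean(.x, w = .data$population)),
      population = sum(.data$population),
      n_countries = n(),
      .groups = "drop"
    )
}

#' Population-weighted regional food-group supplies
#'
#' Converts country-level per-capita supplies into regional per-capita
#' supplies: the region's per-capita energy in each group is the
#' population-weighted mean over member countries present that year,
#' \eqn{\sum_c pop_c q_{c,i} / \sum_c pop_c}. Countries missing a population
#' record or a region assignment for a year are excluded with a warning.
#'
#' @param country_supplies Supply tibble from [group_supply()] with `entity`
#'   holding country codes.
#' @param populations Tibble from [read_population()].
#' @param scheme Tibble from [read_region_scheme()], or `NULL` when
#'   `level = "world"`.
#' @param level `"region"`, `"subregion"`, or `"world"` (a single aggregate
#'   over all countries).
#' @return Supply tibble with `entity` holding region names, plus the summed
#'   `population` and member-country count per row.
#' @export
regional_supply <- function(country_supplies, populations, scheme = NULL,
                            level = c("region", "subregion", "world")) {
  level <- match.arg(level)
  sup <- as_tibble(country_supplies) |>
    left_join(populations, by = c(entity = "country_code", "year"))
  no_pop <- is.na(sup$population)
  if (any(no_pop)) {
    warn(paste0("excluding country-year(s) without population data: ",
                paste(unique(sup$entity[no_pop]), collapse = ", ")))
    sup <- sup[!no_pop, , drop = FALSE]
  }
  if (level == "world") {
    by <- rep("World", nrow(sup))
  } else {
    if (is.null(scheme)) abort("a region scheme is required unless level = 'world'")
    by <- region_lookup(scheme, sup$entity, level = level)
    if (anyNA(by)) {
      sup <- sup[!is.na(by), , drop = FALSE]
      by <- by[!is.na(by)]
    }
  }
  if (nrow(sup) == 0) abort("no country-years left to aggregate")
  weighted_supply(sup, by) |> arrange(.data$entity, .data$year)
}

#' Decade means of country HDBI scores by region, with confidence intervals
#'
#' Each country contributes its average HDBI over the years it has within a
#' decade; the regional point is the unweighted mean of those country
#' averages, with a two-sided t-interval on that mean (standard error across
#' countries, `n - 1` degrees of freedom). With a single country the mean is
#' reported and the interval is undefined (`NA`). Countries not in the
#' scheme are excluded with a warning.
#'
#' @param scores Country-level score tibble from [score_table()].
#' @param scheme Region scheme from [read_region_scheme()].
#' @param decades Decade definitions, as from [hdb_decades()].
#' @param conf_level Confidence level for the interval. Default 0.95.
#' @param min_years Minimum years of data a country needs within a decade to
#'   contribute. Default 1 (any available year counts).
#' @return Tibble of (`region`, `decade`, `mean_hdbi`, `ci_low`, `ci_high`,
#'   `n_countries`).
#' @export
decade_summary <- function(scores, scheme, decades = hdb_decades(),
                           conf_level = 0.95, min_years = 1) {
  stopifnot(all(c("label", "start", "end") %in% names(decades)))
  if (any(decades$start > decades$end)) abort("decade start after end")
  region <- region_lookup(scheme, scores$entity)
  scores <- scores[!is.na(region), , drop = FALSE]
  region <- region[!is.na(region)]
  scores$region <- region
  out <- vector("list", nrow(decades))
  for (d in seq_len(nrow(decades))) {
    span <- scores |>
      filter(.data$year >= decades$start[d], .data$year <= decades$end[d])
    if (nrow(span) == 0) next
    country_means <- span |>
      group_by(.data$region, .data$entity) |>
      summarise(hdbi = mean(.data$hdbi), n_years = n(), .groups = "drop") |>
      filter(.data$n_years >= min_years)
    out[[d]] <- country_means |>
      group_by(.data$region) |>
      summarise(
        decade = decades$label[d],
        mean_hdbi = mean(.data$hdbi),
        n_countries = n(),
        se = if (n() > 1) sd(.data$hdbi) / sqrt(n()) else NA_real_,
        .groups = "drop"
      ) |>
      mutate(
        half = ifelse(.data$n_countries > 1,
                      qt(1 - (1 - conf_level) / 2,
                         df = pmax(.data$n_countries - 1, 1)) * .data$se,
                      NA_real_),
        ci_low = .data$mean_hdbi - .data$half,
        ci_high = .data$mean_hdbi + .data$half
      ) |>
      select("region", "decade", "mean_hdbi", "ci_low", "ci_high", "n_countries")
  }
  empty <- tibble(region = character(), decade = character(),
                  mean_hdbi = double(), ci_low = double(),
                  ci_high = double(), n_countries = integer())
  bind_rows(empty, out)
}

#' Total dietary energy available by region and period
#'
#' Mean daily per-capita kilocalories (the six HDB groups plus sugars;
#' excluded commodities such as spices, beverages and stimulants do not
#' count) over each period's years, for every region and for a `World` row
#' aggregated over all countries. Regional and world values are
#' population-weighted, unlike the unweighted country means of
#' [decade_summary()].
#'
#' @param country_supplies Country-level supply tibble from [group_supply()].
#' @param populations Tibble from [read_population()].
#' @param scheme Region scheme from [read_region_scheme()].
#' @param periods Tibble of (`label`, `start`, `end`); defaults to the
#'   opening (1961--1969) and closing (2020--2022) decades.
#' @return Tibble of (`region`, `period`, `total_kcal`).
#' @export
total_energy <- function(country_supplies, populations, scheme,
                         periods = hdb_decades()[c(1, 7), ]) {
  regional <- regional_supply(country_supplies, populations, scheme, "region")
  world <- regional_supply(country_supplies, populations, NULL, "world")
  levels <- bind_rows(regional, world)
  out <- vector("list", nrow(periods))
  for (p in seq_len(nrow(periods))) {
    span <- levels |>
      filter(.data$year >= periods$start[p], .data$year <= periods$end[p])
    if (nrow(span) == 0) next
    out[[p]] <- span |>
      group_by(region = .data$entity) |>
      summarise(period = periods$label[p],
                total_kcal = mean(.data$total_kcal), .groups = "drop")
  }
  empty <- tibble(region = character(), period = character(),
                  total_kcal = double())
  bind_rows(empty, out) |>
    arrange(.data$period, .data$region != "World", .data$region)
}
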