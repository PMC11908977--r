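#' Configuration for the synthetic food-balance-sheet generator
#'
#' The generator emulates the structure the adequacy analysis assumes:
#' country panels of commodity-level kcal/capita/day following smooth
#' region-specific dietary-transition trends (staples plateauing near target,
#' animal-source foods and oils rising, legumes declining then recovering),
#' each group's energy split across a few synthetic commodities, free sugars
#' and excluded commodities present so mapping logic is exercised, and
#' populations growing at country-specific rates so weighted and unweighted
#' aggregation genuinely differ. It targets structure, not FAOSTAT realism.
#'
#' Group trends follow logistic curves
#' \eqn{level(t) = start + (end - start)/(1 + e^{-rate (t - mid)})} between a
#' start and end level; countries scatter around their region's curve by a
#' fixed lognormal offset. Observation noise is multiplicative lognormal per
#' country-year-commodity, mean-one (\eqn{e^{\sigma Z - \sigma^2/2}}), so
#' `sigma = 0` reproduces the ground truth exactly.
#'
#' @param n_regions Number of world regions (default 7; named after
#'   [hdb_regions()] while available).
#' @param countries_per_region Countries in each region. Default 7.
#' @param years Calendar years of the panel. Default 1961--2022.
#' @param sigma Lognormal noise scale per commodity observation. Default 0.05.
#' @param country_spread Lognormal scatter of country levels around the
#'   region trend. Default 0.10.
#' @param share_concentration Dirichlet-style concentration for commodity
#'   shares within a group (larger = more even). Default 3.
#' @param commodities_per_group Integer range (min, max) of synthetic
#'   commodities per group. Default `c(2, 6)`.
#' @param cutover_year Year at which generated records switch from the
#'   old-era to the new-era label. Default 2010.
#' @param high_income_regions Regions whose countries receive no scenario
#'   trajectories (held at base in projections). Default `"North America"`.
#' @param region_profiles Optional tibble of trend parameters (`archetype`,
#'   `group`, `start`, `end`, `mid`, `rate`) overriding the defaults.
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_regions = 7, countries_per_region = 7,
                       years = 1961:2022, sigma = 0.05,
                       country_spread = 0.10, share_concentration = 3,
                       commodities_per_group = c(2, 6), cutover_year = 2010,
                       high_income_regions = "North America",
                       region_profiles = NULL, seed = 1) {
  if (n_regions < 1 || countries_per_region < 1) {
    abort("n_regions and countries_per_region must be at least 1")
  }
  if (sigma < 0 || country_spread < 0 || share_concentration <= 0) {
    abort("sigma and country_spread must be >= 0; share_concentration > 0")
  }
  if (length(commodities_per_group) != 2 ||
      commodities_per_group[1] < 1 ||
      commodities_per_group[1] > commodities_per_group[2]) {
    abort("commodities_per_group must be an increasing pair of positive integers")
  }
  structure(
    list(n_regions = n_regions, countries_per_region = countries_per_region,
         years = as.integer(years), sigma = sigma,
         country_spread = country_spread,
         share_concentration = share_concentration,
         commodities_per_group = as.integer(commodities_per_group),
         cutover_year = cutover_year,
         high_income_regions = high_income_regions,
         region_profiles = region_profiles %||% default_region_profiles(),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Trend archetypes (kcal/capita/day): start level, end level, logistic
# midpoint year and rate, for the six groups plus SUGAR and EXCLUDED.
# Archetypes loosely follow the canonical regional transition narratives:
# rapid East-Asian diversification, affluent plateaus, South-Asian legume
# decline, slow Sub-Saharan change.
default_region_profiles <- function() {
  p <- function(a, g, s, e, m, r) {
    tibble(archetype = a, group = g, start = s, end = e, mid = m, rate = r)
  }
  bind_rows(
    # 1: rapid transition, staples off a high peak, vegetables boom
    p(1, "starchy_staples", 1450, 1250, 1990, 0.10),
    p(1, "fruits", 30, 150, 1995, 0.12),
    p(1, "vegetables", 40, 260, 1995, 0.15),
    p(1, "animal_source_foods", 80, 420, 1998, 0.10),
    p(1, "legumes_nuts_seeds", 150, 120, 1980, 0.08),
    p(1, "oils_fats", 80, 280, 1995, 0.10),
    p(1, "SUGAR", 60, 200, 1995, 0.08),
    p(1, "EXCLUDED", 40, 70, 1990, 0.06),
    # 2: affluent, staples declining to target, high animal-source foods
    p(2, "starchy_staples", 1400, 1150, 1975, 0.12),
    p(2, "fruits", 100, 160, 1990, 0.08),
    p(2, "vegetables", 90, 140, 1990, 0.08),
    p(2, "animal_source_foods", 500, 600, 1985, 0.08),
    p(2, "legumes_nuts_seeds", 60, 75, 2005, 0.08),
    p(2, "oils_fats", 250, 350, 1990, 0.08),
    p(2, "SUGAR", 300, 280, 1985, 0.06),
    p(2, "EXCLUDED", 70, 90, 1985, 0.06),
    # 3: middle-income, sugar-heavy, meat rising
    p(3, "starchy_staples", 1100, 1150, 1990, 0.06),
    p(3, "fruits", 120, 160, 1995, 0.08),
    p(3, "vegetables", 40, 75, 1995, 0.08),
    p(3, "animal_source_foods", 250, 460, 1995, 0.08),
    p(3, "legumes_nuts_seeds", 130, 100, 1985, 0.08),
    p(3, "oils_fats", 150, 300, 1992, 0.09),
    p(3, "SUGAR", 350, 330, 1985, 0.05),
    p(3, "EXCLUDED", 50, 75, 1990, 0.06),
    # 4: high-income, oils and sugar far above target
    p(4, "starchy_staples", 900, 1060, 1995, 0.07),
    p(4, "fruits", 100, 130, 1990, 0.07),
    p(4, "vegetables", 70, 95, 1990, 0.07),
    p(4, "animal_source_foods", 600, 650, 1985, 0.07),
    p(4, "legumes_nuts_seeds", 90, 125, 2000, 0.08),
    p(4, "oils_fats", 350, 640, 1995, 0.08),
    p(4, "SUGAR", 450, 500, 1990, 0.06),
    p(4, "EXCLUDED", 90, 110, 1990, 0.06),
    # 5: staple-centred, legumes declining from high levels, oils surging
    p(5, "starchy_staples", 1330, 1410, 1995, 0.06),
    p(5, "fruits", 30, 95, 2005, 0.09),
    p(5, "vegetables", 30, 85, 2005, 0.09),
    p(5, "animal_source_foods", 120, 260, 2005, 0.08),
    p(5, "legumes_nuts_seeds", 190, 100, 1985, 0.09),
    p(5, "oils_fats", 90, 300, 2005, 0.09),
    p(5, "SUGAR", 160, 205, 1990, 0.07),
    p(5, "EXCLUDED", 25, 45, 1995, 0.06),
    # 6: slow change, staples adequate, deep shortfalls elsewhere
    p(6, "starchy_staples", 1190, 1300, 1995, 0.05),
    p(6, "fruits", 70, 85, 1995, 0.05),
    p(6, "vegetables", 30, 45, 1995, 0.05),
    p(6, "animal_source_foods", 115, 135, 1995, 0.05),
    p(6, "legumes_nuts_seeds", 130, 165, 2005, 0.07),
    p(6, "oils_fats", 120, 185, 2000, 0.06),
    p(6, "SUGAR", 95, 115, 1995, 0.05),
    p(6, "EXCLUDED", 25, 40, 1995, 0.05),
    # 7: staples rising above target, fast oil growth
    p(7, "starchy_staples", 1290, 1450, 1985, 0.08),
    p(7, "fruits", 100, 145, 1995, 0.07),
    p(7, "vegetables", 60, 115, 1995, 0.08),
    p(7, "animal_source_foods", 150, 300, 1995, 0.08),
    p(7, "legumes_nuts_seeds", 95, 80, 1985, 0.06),
    p(7, "oils_fats", 150, 330, 1990, 0.09),
    p(7, "SUGAR", 250, 285, 1985, 0.06),
    p(7, "EXCLUDED", 45, 65, 1990, 0.06)
  )
}

logistic_level <- function(start, end, mid, rate, year) {
  start + (end - start) / (1 + exp(-rate * (year - mid)))
}

# Deterministic ISO3-style synthetic country codes: "SAA", "SAB", ...
make_country_codes <- function(n) {
  if (n > 26 * 26) abort("too many synthetic countries requested")
  i <- seq_len(n) - 1L
  paste0("S", LETTERS[i %/% 26 + 1], LETTERS[i %% 26 + 1])
}

# Region/subregion layout is deterministic (no RNG): regions reuse the
# default seven names while available, countries round-robin over two
# subregions per region.
sim_scheme <- function(config) {
  base_names <- hdb_regions()
  region_names <- if (config$n_regions <= length(base_names)) {
    base_names[seq_len(config$n_regions)]
  } else {
    c(base_names, paste("Region", seq(length(base_names) + 1, config$n_regions)))
  }
  n <- config$n_regions * config$countries_per_region
  codes <- make_country_codes(n)
  region <- rep(region_names, each = config$countries_per_region)
  sub_idx <- rep_len(c("A", "B"), config$countries_per_region)
  scheme <- tibble(
    country_code = codes,
    subregion = paste0(region, " (", rep(sub_idx, config$n_regions), ")"),
    region = region
  )
  attr(scheme, "regions") <- region_names
  scheme
}

#' Simulate a food-balance-sheet panel with ground truth
#'
#' Generates commodity-level records (old- and new-era labels split at the
#' configured cutover year), a population table, a region scheme, a
#' commodity mapping covering the synthetic commodities, and the ground
#' truth: the true per-country-year food-group supplies before commodity
#' splitting and noise, plus the true HDBI scores. With `sigma = 0` the
#' records sum back to the truth exactly; all output is deterministic under
#' the config seed.
#'
#' @param config A [sim_config()].
#' @return List with elements `records`, `populations`, `scheme`, `mapping`,
#'   `truth` (list of `supply` and `scores`), and `config`.
#' @export
simulate_fbs <- function(config) {
  if (!inherits(config, "sim_config")) abort("config must come from sim_config()")
  withr::with_seed(config$seed, simulate_fbs_impl(config))
}

simulate_fbs_impl <- function(config) {
  groups <- hdb_groups()
  trend_groups <- c(groups, "SUGAR", "EXCLUDED")
  scheme <- sim_scheme(config)
  countries <- scheme$country_code
  n_country <- length(countries)
  years <- config$years

  # region trend parameters: recycle archetypes over configured regions
  prof <- config$region_profiles
  arch <- ((seq_len(config$n_regions) - 1) %% max(prof$archetype)) + 1
  region_par <- tibble(region = attr(scheme, "regions"), archetype = arch) |>
    left_join(prof, by = "archetype", relationship = "many-to-many")

  # fixed lognormal country offsets around the region curve, per group
  offsets <- tidyr::crossing(country_code = countries, group = trend_groups) |>
    mutate(offset = exp(rnorm(n(), 0, config$country_spread)))

  truth_long <- scheme |>
    select("country_code", "region") |>
    left_join(region_par, by = "region", relationship = "many-to-many") |>
    tidyr::crossing(year = years) |>
    left_join(offsets, by = c("country_code", "group")) |>
    mutate(kcal = logistic_level(.data$start, .data$end, .data$mid,
                                 .data$rate, .data$year) * .data$offset) |>
    select("country_code", "year", "group", "kcal")

  truth_supply <- truth_long |>
    tidyr::pivot_wider(names_from = "group", values_from = "kcal") |>
    rename(entity = "country_code", sugar_kcal = "SUGAR",
           excluded_kcal = "EXCLUDED") |>
    mutate(total_kcal = rowSums(across(all_of(groups))) + .data$sugar_kcal) |>
    select(all_of(c("entity", "year", groups,
                    "sugar_kcal", "excluded_kcal", "total_kcal"))) |>
    arrange(.data$entity, .data$year)
  truth_scores <- score_table(truth_supply)

  # synthetic commodity list: 2-6 commodities per group, shared mapping
  n_per <- sapply(trend_groups, function(g) {
    sample(seq(config$commodities_per_group[1],
               config$commodities_per_group[2]), 1)
  })
  mapping <- bind_rows(lapply(seq_along(trend_groups), function(i) {
    g <- trend_groups[i]
    k <- seq_len(n_per[i])
    tibble(
      commodity_code = sprintf("S%02d%02d", i, k),
      commodity_name = paste0("Synthetic ", gsub("_", " ", tolower(g)), " ", k),
      display_aggregate = paste0("synthetic ", gsub("_", " ", tolower(g))),
      group = g
    )
  }))

  # country-specific Dirichlet shares over each group's commodities,
  # constant across years
  shares <- tidyr::crossing(country_code = countries,
                            mapping |> select("commodity_code", "group")) |>
    mutate(w = rgamma(n(), shape = config$share_concentration, rate = 1)) |>
    group_by(.data$country_code, .data$group) |>
    mutate(share = .data$w / sum(.data$w)) |>
    ungroup() |>
    select(-"w")

  records <- truth_long |>
    inner_join(shares, by = c("country_code", "group"),
               relationship = "many-to-many") |>
    left_join(mapping |> select("commodity_code", "commodity_name"),
              by = "commodity_code")
  noise <- if (config$sigma > 0) {
    exp(rnorm(nrow(records), 0, config$sigma) - config$sigma^2 / 2)
  } else {
    1
  }
  records <- records |>
    mutate(kcal = .data$kcal * .data$share * noise,
           era = ifelse(.data$year < config$cutover_year, "old", "new")) |>
    select("country_code", "year", "commodity_code", "commodity_name",
           "kcal", "era") |>
    arrange(.data$country_code, .data$year, .data$commodity_code)

  populations <- tibble(country_code = countries,
                        pop0 = runif(n_country, 5e6, 1.5e8),
                        growth = runif(n_country, 0.003, 0.028)) |>
    tidyr::crossing(year = years) |>
    mutate(population = .data$pop0 * exp(.data$growth * (.data$year - min(years)))) |>
    select("country_code", "year", "population") |>
    arrange(.data$country_code, .data$year)

  list(records = records, populations = populations, scheme = scheme,
       mapping = mapping, truth = list(supply = truth_supply,
                                       scores = truth_scores),
       config = config)
}

#' Simulate scenario percentage-change trajectories
#'
#' Generates reference and increased-investment trajectories for the
#' countries of a [sim_config()] layout: smooth monotone deltas from 0 at the
#' base year, with investment deltas at least as large as reference deltas
#' for the investment-targeted groups (starchy staples, animal-source foods,
#' legumes/nuts/seeds, oils and fats) and identical income-driven deltas for
#' fruits and vegetables, which the modeled investments reach only
#' indirectly. Countries in `config$high_income_regions` receive no rows and
#' are therefore held at base by [apply_changes()].
#'
#' @param config A [sim_config()].
#' @param years Projection years. Default 2010 to 2050 in 5-year steps.
#' @param base_year Base year with delta 0. Default 2010.
#' @param ssp,rcp Scenario-family labels recorded on every row.
#' @param seed Seed; defaults to `config$seed + 1` so trajectories are
#'   independent of the panel draw but still reproducible.
#' @return Trajectory tibble as consumed by [apply_changes()].
#' @export
simulate_trajectories <- function(config, years = seq(2010, 2050, by = 5),
                                  base_year = 2010, ssp = "SSP3",
                                  rcp = "RCP8.5", seed = config$seed + 1L) {
  if (!inherits(config, "sim_config")) abort("config must come from sim_config()")
  targeted <- c("starchy_staples", "animal_source_foods",
                "legumes_nuts_seeds", "oils_fats")
  scheme <- sim_scheme(config)
  units <- scheme$country_code[!scheme$region %in% config$high_income_regions]
  horizon <- max(years)
  ramp <- (1 - exp(-0.06 * (years - base_year))) /
    (1 - exp(-0.06 * (horizon - base_year)))
  withr::with_seed(seed, {
    ends <- tidyr::crossing(unit = units, group = hdb_groups()) |>
      mutate(
        end_ref = ifelse(.data$group %in% targeted,
                         runif(n(), 0.05, 0.25), runif(n(), 0.05, 0.30)),
        uplift = ifelse(.data$group %in% targeted, runif(n(), 0.05, 0.15), 0),
        end_inv = .data$end_ref + .data$uplift
      )
    bind_rows(
      ends |> mutate(scenario = "reference", end = .data$end_ref),
      ends |> mutate(scenario = "increased_investments", end = .data$end_inv)
    ) |>
      tidyr::crossing(tibble(year = years, ramp = ramp)) |>
      mutate(ssp = ssp, rcp = rcp, delta = .data$end * .data$ramp) |>
      select("scenario", "ssp", "rcp", "unit", "group", "year", "delta") |>
      arrange(.data$scenario, .data$unit, .data$group, .data$year)
  })
}

#' Write a simulated panel in the file dialects the readers consume
#'
#' Serializes a [simulate_fbs()] result as delimited text: old- and new-era
#' supply tables in their respective export dialects, plus population,
#' region-scheme, and commodity-mapping files. Fixtures written this way
#' exercise the real readers end to end.
#'
#' @param sim Result of [simulate_fbs()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths (`supply_old`, `supply_new`,
#'   `population`, `scheme`, `mapping`).
#' @export
write_fbs_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    supply_old = file.path(dir, "supply_old.csv"),
    supply_new = file.path(dir, "supply_new.csv"),
    population = file.path(dir, "population.csv"),
    scheme = file.path(dir, "region_scheme.csv"),
    mapping = file.path(dir, "commodity_mapping.csv")
  )
  dialect <- function(recs, country_col) {
    n <- nrow(recs)
    out <- data.frame(recs$country_code, recs$country_code,
                      recs$commodity_code, recs$commodity_name,
                      rep(664L, n), rep("Food supply (kcal/capita/day)", n),
                      recs$year, rep("kcal/capita/day", n), recs$kcal,
                      check.names = FALSE)
    names(out) <- c(country_col[1], country_col[2], "Item Code", "Item",
                    "Element Code", "Element", "Year", "Unit", "Value")
    out
  }
  old <- sim$records |> filter(.data$era == "old")
  new <- sim$records |> filter(.data$era == "new")
  readr::write_csv(dialect(old, c("Country Code", "Country")), paths$supply_old)
  readr::write_csv(dialect(new, c("Area Code (ISO3)", "Area")), paths$supply_new)
  readr::write_csv(sim$populations, paths$population)
  readr::write_csv(sim$scheme, paths$scheme)
  readr::write_csv(sim$mapping, paths$mapping)
  paths
}
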