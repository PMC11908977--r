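#' Load scenario percentage-change trajectories
#'
#' Reads a table of projected proportional changes in food-group availability
#' relative to a base year, as produced by partial-equilibrium agricultural
#' models run under scenario families (investment scenario x shared
#' socioeconomic pathway x climate pathway). A `delta` of `0.10` means that
#' unit's availability of that group is 10% above its base-year level.
#'
#' @param path CSV with columns `scenario`, `ssp`, `rcp`, `unit`, `group`,
#'   `year`, `delta`.
#' @param base_year Reference year every trajectory must include with
#'   `delta = 0`. Default 2010.
#' @return Validated trajectory tibble.
#' @export
load_trajectories <- function(path, base_year = 2010) {
  if (!file.exists(path)) abort(paste0("trajectory file not found: ", path))
  tab <- readr::read_csv(path, show_col_types = FALSE)
  miss <- setdiff(c("scenario", "ssp", "rcp", "unit", "group", "year", "delta"),
                  names(tab))
  if (length(miss)) {
    abort(paste0("trajectory file is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  tab$year <- as.integer(tab$year)
  tab$delta <- as.numeric(tab$delta)
  validate_trajectories(as_tibble(tab), base_year = base_year)
}

validate_trajectories <- function(traj, base_year = 2010) {
  if (any(!is.finite(traj$delta)) || any(traj$delta < -1)) {
    abort("trajectory delta must be finite and >= -1 (cannot lose more than all supply)")
  }
  unknown <- setdiff(unique(traj$group), hdb_groups())
  if (length(unknown)) {
    abort(paste0("trajectory group(s) not HDB groups: ",
                 paste(unknown, collapse = ", ")))
  }
  key <- c("scenario", "ssp", "rcp", "unit", "group", "year")
  if (anyDuplicated(traj[key])) {
    abort("duplicate (scenario, ssp, rcp, unit, group, year) in trajectories")
  }
  base <- traj |> filter(.data$year == base_year)
  series <- traj |> distinct(.data$scenario, .data$ssp, .data$rcp,
                             .data$unit, .data$group)
  base_keys <- base |> distinct(.data$scenario, .data$ssp, .data$rcp,
                                .data$unit, .data$group)
  if (nrow(base_keys) < nrow(series)) {
    abort(sprintf("every trajectory series must include the base year %d",
                  base_year))
  }
  if (any(abs(base$delta) > 1e-12)) {
    abort(sprintf("base-year (%d) delta must be 0", base_year))
  }
  traj
}

#' Project food-group supplies and HDBI under scenario trajectories
#'
#' Applies cumulative proportional changes to an observed base-year supply:
#' projected \eqn{q_i(t) = q_i(base) \times (1 + \delta_i(t))}, with the HDBI
#' recomputed on the projected vector. Deltas are relative to the base year,
#' not chained year-on-year growth rates (`chained = TRUE` switches to the
#' chained reading, compounding successive rows of each series). Groups
#' without a trajectory row for a unit-year, and free sugars, are held at
#' base level.
#'
#' @param base Supply tibble (as from [group_supply()] or
#'   [combine_country_aggregates()]) restricted to the base year; `entity`
#'   must match trajectory `unit` identifiers. Units without any trajectory
#'   are carried through at base level for every projection year.
#' @param traj Trajectory tibble from [load_trajectories()] or
#'   [simulate_trajectories()].
#' @param targets HDB targets for the recomputed index.
#' @param base_year Base year of both the supply rows and the deltas.
#' @param chained Interpret deltas as year-on-year growth rates instead of
#'   cumulative change from base. Default `FALSE`.
#' @return Tibble of (`unit`, `scenario`, `ssp`, `rcp`, `year`, the six
#'   projected group columns, `sugar_kcal`, `total_kcal`, `hdbi`).
#' @export
apply_changes <- function(base, traj, targets = hdb_targets(),
                          base_year = 2010, chained = FALSE) {
  groups <- hdb_groups()
  base <- as_tibble(base) |> filter(.data$year == base_year)
  if (nrow(base) == 0) abort(sprintf("base supply has no rows for %d", base_year))
  miss <- setdiff(groups, names(base))
  if (length(miss)) {
    abort(paste0("base supply is missing group column(s): ",
                 paste(miss, collapse = ", ")))
  }
  traj <- validate_trajectories(traj, base_year = base_year)
  scenarios <- traj |> distinct(.data$scenario, .data$ssp, .data$rcp)
  years <- sort(unique(traj$year))
  grid <- tidyr::crossing(scenarios, unit = base$entity, year = years)
  long <- grid |>
    tidyr::crossing(group = groups) |>
    left_join(traj, by = c("scenario", "ssp", "rcp", "unit", "group", "year"))
  if (chained) {
    long <- long |>
      mutate(delta = coalesce(.data$delta, 0)) |>
      group_by(.data$scenario, .data$ssp, .data$rcp, .data$unit, .data$group) |>
      arrange(.data$year, .by_group = TRUE) |>
      mutate(factor = cumprod(1 + .data$delta)) |>
      ungroup()
  } else {
    long <- long |> mutate(factor = 1 + coalesce(.data$delta, 0))
  }
  base_long <- base |>
    select(unit = "entity", all_of(groups),
           any_of(c("sugar_kcal", "total_kcal"))) |>
    tidyr::pivot_longer(all_of(groups), names_to = "group", values_to = "q0")
  proj <- long |>
    inner_join(base_long, by = c("unit", "group")) |>
    mutate(q = .data$q0 * .data$factor)
  wide <- proj |>
    select(any_of(c("unit", "scenario", "ssp", "rcp", "year", "group", "q",
                    "sugar_kcal"))) |>
    tidyr::pivot_wider(names_from = "group", values_from = "q")
  if (!"sugar_kcal" %in% names(wide)) wide$sugar_kcal <- NA_real_
  wide$total_kcal <- rowSums(wide[groups]) +
    ifelse(is.na(wide$sugar_kcal), 0, wide$sugar_kcal)
  scored <- score_table(
    wide |> rename(entity = "unit"), targets = targets)
  wide$hdbi <- scored$hdbi
  wide |>
    select(all_of(c("unit", "scenario", "ssp", "rcp", "year", groups,
                    "sugar_kcal", "total_kcal", "hdbi"))) |>
    arrange(.data$scenario, .data$ssp, .data$rcp, .data$unit, .data$year)
}

#' Combine member countries into a model country-aggregate supply
#'
#' Scenario models often report trajectories for multi-country aggregates
#' (e.g. "Baltic States"). This builds the aggregate's base-year per-capita
#' supply as the population-weighted mean over its members, using base-year
#' populations only. If any intended member lacks a base-year supply row or
#' population, the aggregate is skipped with a warning and `NULL` is
#' returned, since a partial aggregate would misstate per-capita levels.
#'
#' @param member_supplies Country-level supply tibble at the base year.
#' @param pop_base Population tibble restricted to (or at least covering)
#'   the base year.
#' @param members Character vector of member country codes.
#' @param aggregate_id Identifier for the combined unit.
#' @param base_year Base year. Default 2010.
#' @return One-row supply tibble with `entity = aggregate_id`, or `NULL`
#'   when a member is missing.
#' @export
combine_country_aggregates <- function(member_supplies, pop_base, members,
                                       aggregate_id, base_year = 2010) {
  sup <- as_tibble(member_supplies) |>
    filter(.data$year == base_year, .data$entity %in% members)
  pop <- pop_base |> filter(.data$year == base_year, .data$country_code %in% members)
  missing <- setdiff(members, intersect(sup$entity, pop$country_code))
  if (length(missing)) {
    warn(paste0("aggregate '", aggregate_id,
                "' skipped; member(s) missing base-year data: ",
                paste(missing, collapse = ", ")))
    return(NULL)
  }
  sup <- sup |> left_join(pop, by = c(entity = "country_code", "year"))
  cols <- supply_value_cols(sup)
  out <- tibble(entity = aggregate_id, year = as.integer(base_year))
  for (cl in cols) out[[cl]] <- weighted.mean(sup[[cl]], w = sup$population)
  out
}

#' Summarize projected HDBI by region, scenario and year
#'
#' Unweighted mean of unit-level projected HDBI per region-scenario-year,
#' plus a `World` row averaging over all units, mirroring how historical
#' regional scores are reported as means of countries.
#'
#' @param results Projection tibble from [apply_changes()].
#' @param scheme Region scheme mapping units to regions; units not in the
#'   scheme (e.g. model aggregates spanning regions) are kept only in the
#'   `World` mean, with a warning.
#' @return Tibble of (`region`, `scenario`, `ssp`, `rcp`, `year`,
#'   `mean_hdbi`, `n_units`).
#' @export
project_summary <- function(results, scheme) {
  region <- region_lookup(scheme, results$unit)
  by_region <- results |>
    mutate(region = region) |>
    filter(!is.na(region)) |>
    group_by(.data$region, .data$scenario, .data$ssp, .data$rcp, .data$year) |>
    summarise(mean_hdbi = mean(.data$hdbi), n_units = n(), .groups = "drop")
  world <- results |>
    group_by(.data$scenario, .data$ssp, .data$rcp, .data$year) |>
    summarise(mean_hdbi = mean(.data$hdbi), n_units = n(), .groups = "drop") |>
    mutate(region = "World", .before = 1)
  bind_rows(by_region, world) |>
    arrange(.data$scenario, .data$ssp, .data$rcp,
            .data$region != "World", .data$region, .data$year)
}
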