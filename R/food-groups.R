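.group_labels <- function() c(hdb_groups(), "SUGAR", "EXCLUDED")

#' Load a commodity-to-food-group mapping
#'
#' Each commodity maps to exactly one label: one of the six HDB groups,
#' `SUGAR` (free sugars, assessed against the WHO limit rather than a basket
#' target), or `EXCLUDED` (spices, beverages, stimulants, infant foods and
#' similar items outside the basket and outside reported energy totals). An
#' optional `display_aggregate` groups minor commodities for composition
#' reporting (e.g. yams within "other roots"; demersal, pelagic and other
#' marine fish within "other marine fish").
#'
#' The bundled default covers the standard food-balance-sheet item list with
#' best-effort assignments: cereals, roots, tubers and plantains to starchy
#' staples; bananas to fruits; pulses, nuts and oilcrops eaten as food to
#' legumes/nuts/seeds; vegetable oils and animal fats to oils and fats; sugar
#' and sweeteners to `SUGAR`; alcohol, stimulants and spices to `EXCLUDED`.
#' It is data, not code: supply your own file to override any assignment.
#'
#' @param path CSV with columns `commodity_code`, `commodity_name`,
#'   `display_aggregate`, `group`; `NULL` loads the bundled default.
#' @return Validated mapping tibble.
#' @export
load_mapping <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hdb_commodity_mapping.csv",
                        package = "hdbindex", mustWork = TRUE)
  }
  if (!file.exists(path)) abort(paste0("mapping file not found: ", path))
  tab <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  miss <- setdiff(c("commodity_code", "group"), names(tab))
  if (length(miss)) {
    abort(paste0("mapping file is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  out <- tibble(
    commodity_code = as.character(tab$commodity_code),
    commodity_name = if ("commodity_name" %in% names(tab)) {
      tab$commodity_name
    } else {
      tab$commodity_code
    },
    display_aggregate = if ("display_aggregate" %in% names(tab)) {
      tab$display_aggregate
    } else {
      NA_character_
    },
    group = tab$group
  )
  out$display_aggregate <- coalesce(out$display_aggregate, out$commodity_name)
  if (anyDuplicated(out$commodity_code)) {
    dup <- out$commodity_code[duplicated(out$commodity_code)][1]
    abort(paste0("duplicate commodity code in mapping: ", dup))
  }
  unknown <- setdiff(unique(out$group), .group_labels())
  if (length(unknown)) {
    abort(paste0("unknown group label(s) in mapping: ",
                 paste(unknown, collapse = ", ")))
  }
  out
}

# Join records to their mapping; unmapped commodities become EXCLUDED in
# non-strict mode (with a warning), or raise an error listing the codes.
map_records <- function(records, mapping, strict = FALSE) {
  idx <- match(as.character(records$commodity_code),
               as.character(mapping$commodity_code))
  if (anyNA(idx)) {
    codes <- sort(unique(records$commodity_code[is.na(idx)]))
    msg <- paste0("commodity code(s) not in mapping: ",
                  paste(codes, collapse = ", "))
    if (strict) abort(msg)
    warn(paste0(msg, "; treated as EXCLUDED"))
  }
  records$group <- ifelse(is.na(idx), "EXCLUDED", mapping$group[idx])
  records$display_aggregate <- ifelse(
    is.na(idx), records$commodity_name, mapping$display_aggregate[idx])
  records
}

#' Aggregate commodity records to HDB food-group supplies
#'
#' Sums kilocalories over commodities within each HDB group per entity-year,
#' giving the supply vector \eqn{q_i} that [score_table()] compares against
#' the basket targets. `SUGAR` commodities accumulate into `sugar_kcal`;
#' `EXCLUDED` commodities accumulate into `excluded_kcal` and contribute to
#' neither any group nor `total_kcal`, which covers the six groups plus
#' sugar only.
#'
#' @param records Record tibble from [read_supply_table()] / [merge_eras()].
#' @param mapping Mapping tibble from [load_mapping()].
#' @param strict Error on commodities absent from the mapping instead of
#'   treating them as `EXCLUDED` with a warning.
#' @return Tibble with columns `entity`, `year`, one column per HDB group,
#'   `sugar_kcal`, `excluded_kcal`, `total_kcal`.
#' @export
group_supply <- function(records, mapping, strict = FALSE) {
  groups <- hdb_groups()
  empty <- tibble(entity = character(), year = integer())
  for (g in groups) empty[[g]] <- double()
  empty$sugar_kcal <- double(); empty$excluded_kcal <- double()
  empty$total_kcal <- double()
  if (nrow(records) == 0) return(empty)
  mapped <- map_records(records, mapping, strict = strict)
  wide <- mapped |>
    group_by(entity = .data$country_code, year = .data$year, group = .data$group) |>
    summarise(kcal = sum(.data$kcal), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group", values_from = "kcal",
                       values_fill = 0)
  for (g in c(groups, "SUGAR", "EXCLUDED")) {
    if (!g %in% names(wide)) wide[[g]] <- 0
  }
  wide |>
    rename(sugar_kcal = "SUGAR", excluded_kcal = "EXCLUDED") |>
    mutate(total_kcal = rowSums(across(all_of(groups))) + .data$sugar_kcal) |>
    select(all_of(c("entity", "year", groups,
                    "sugar_kcal", "excluded_kcal", "total_kcal"))) |>
    arrange(.data$entity, .data$year)
}

#' Food-group composition by display aggregate
#'
#' Kilocalories per entity-year by display aggregate, for reporting which
#' commodities carry each group (e.g. the dominance of wheat and rice within
#' starchy staples). Within any group the aggregate rows sum exactly to that
#' group's supply in [group_supply()].
#'
#' @inheritParams group_supply
#' @return Tibble of (`entity`, `year`, `display_aggregate`, `group`,
#'   `kcal`), covering the six HDB groups plus `SUGAR` and `EXCLUDED`.
#' @export
composition <- function(records, mapping, strict = FALSE) {
  if (nrow(records) == 0) {
    return(tibble(entity = character(), year = integer(),
                  display_aggregate = character(), group = character(),
                  kcal = double()))
  }
  map_records(records, mapping, strict = strict) |>
    group_by(entity = .data$country_code, year = .data$year,
             display_aggregate = .data$display_aggregate, group = .data$group) |>
    summarise(kcal = sum(.data$kcal), .groups = "drop") |>
    arrange(.data$entity, .data$year, .data$group, .data$display_aggregate)
}
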