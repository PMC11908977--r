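#' The six Healthy Diet Basket food groups
#'
#' Canonical machine-readable names for the six HDB food groups, in the order
#' used throughout the package. Supply tables carry one column per group under
#' these names; `SUGAR` and `EXCLUDED` are reserved labels for free sugars and
#' for commodities outside the basket (spices, beverages, stimulants, ...).
#'
#' @return Character vector of length six.
#' @export
#' @examples
#' hdb_groups()
hdb_groups <- function() {
  c("starchy_staples", "fruits", "vegetables",
    "animal_source_foods", "legumes_nuts_seeds", "oils_fats")
}

#' Default seven-region world scheme names
#'
#' The seven world regions used for regional reporting, formed by combining
#' United Nations geoscheme subregions. Region names are configuration, not a
#' closed set: [read_region_scheme()] accepts any list of region names.
#'
#' @return Character vector of length seven.
#' @export
hdb_regions <- function() {
  c("East Asia & Pacific", "Europe & Central Asia",
    "Latin America & Caribbean", "North America", "South Asia",
    "Sub-Saharan Africa", "Western Asia & North Africa")
}

# Benchmark kilocalories per capita per day for each HDB group (total 2330,
# the energy needs of a reference adult woman).
.hdb_default_targets <- c(
  starchy_staples     = 1160,
  fruits              = 160,
  vegetables          = 110,
  animal_source_foods = 300,
  legumes_nuts_seeds  = 300,
  oils_fats           = 300
)

#' Healthy Diet Basket kilocalorie targets
#'
#' Benchmark daily per-capita dietary energy for each of the six HDB food
#' groups (the \eqn{Q_i} of the adequacy index). The default basket allocates
#' 1160 kcal to starchy staples, 160 to fruits, 110 to vegetables, and 300
#' each to animal-source foods, legumes/nuts/seeds, and oils and fats, summing
#' to 2330 kcal/day. Alternative targets can be supplied from a delimited file
#' with columns `group` and `target_kcal`.
#'
#' @param path Optional path to a CSV file of targets. `NULL` returns the
#'   bundled defaults.
#' @param total_kcal Expected sum of the six targets, used as a consistency
#'   check. Default 2330.
#' @return Named numeric vector over the six groups of [hdb_groups()].
#' @export
#' @examples
#' hdb_targets()
#' sum(hdb_targets())
hdb_targets <- function(path = NULL, total_kcal = 2330) {
  if (is.null(path)) {
    targets <- .hdb_default_targets
  } else {
    if (!file.exists(path)) abort(paste0("targets file not found: ", path))
    tab <- readr::read_csv(path, show_col_types = FALSE)
    need <- c("group", "target_kcal")
    miss <- setdiff(need, names(tab))
    if (length(miss)) {
      abort(paste0("targets file is missing column(s): ",
                   paste(miss, collapse = ", ")))
    }
    targets <- setNames(as.numeric(tab$target_kcal), tab$group)
  }
  validate_targets(targets, total_kcal = total_kcal)
  targets[hdb_groups()]
}

validate_targets <- function(targets, total_kcal = 2330) {
  groups <- hdb_groups()
  miss <- setdiff(groups, names(targets))
  if (length(miss)) {
    abort(paste0("targets must cover all six HDB groups; missing: ",
                 paste(miss, collapse = ", ")))
  }
  extra <- setdiff(names(targets), groups)
  if (length(extra)) {
    abort(paste0("unknown group(s) in targets: ", paste(extra, collapse = ", ")))
  }
  if (any(!is.finite(targets)) || any(targets <= 0)) {
    abort("all HDB targets must be positive and finite")
  }
  if (!is.null(total_kcal) &&
      abs(sum(targets) - total_kcal) > 1e-6) {
    abort(sprintf("HDB targets sum to %.6g, expected %.6g",
                  sum(targets), total_kcal))
  }
  invisible(targets)
}
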