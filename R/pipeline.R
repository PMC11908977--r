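#' Load a pipeline configuration
#'
#' A pipeline config can be a YAML file or a list with the same shape:
#'
#' ```yaml
#' out_dir: out
#' seed: 1
#' strict: false
#' cutover_year: 2010
#' base_year: 2010
#' sim: {n_regions: 7, countries_per_region: 7, sigma: 0.05}
#' paths:
#'   supply_old: inputs/supply_old.csv
#'   supply_new: inputs/supply_new.csv
#'   population: inputs/population.csv
#'   scheme: inputs/region_scheme.csv
#'   mapping: inputs/commodity_mapping.csv   # omit for the bundled default
#'   targets: inputs/targets.csv             # omit for the bundled default
#'   trajectories: inputs/trajectories.csv
#' decades: [{label: 1960s, start: 1961, end: 1969}, ...]
#' ```
#'
#' Relative paths are resolved against the config file's directory.
#'
#' @param config Path to a YAML file, or a list.
#' @return Normalized config list.
#' @export
load_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    base_dir <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
    config$paths <- lapply(config$paths, function(p) {
      if (!is.null(p) && !grepl("^(/|[A-Za-z]:)", p)) file.path(base_dir, p) else p
    })
    if (!is.null(config$out_dir) && !grepl("^(/|[A-Za-z]:)", config$out_dir)) {
      config$out_dir <- file.path(base_dir, config$out_dir)
    }
  }
  if (is.null(config$out_dir)) abort("config must set out_dir")
  config$seed <- as.integer(config$seed %||% 1L)
  config$strict <- isTRUE(config$strict)
  config$cutover_year <- config$cutover_year %||% 2010
  config$base_year <- config$base_year %||% 2010
  dec <- config$decades
  config$decades <- if (is.null(dec)) {
    hdb_decades()
  } else if (is.data.frame(dec)) {
    as_tibble(dec)
  } else {
    bind_rows(lapply(dec, as_tibble))
  }
  if (nrow(config$decades) > 1) {
    d <- config$decades[order(config$decades$start), ]
    if (any(d$end[-nrow(d)] >= d$start[-1])) abort("decade spans overlap")
  }
  config
}

read_artifact <- function(state, name, path, loader, stage) {
  if (!is.null(state[[name]])) return(state[[name]])
  if (!is.null(path) && file.exists(path)) return(loader(path))
  abort(sprintf("stage '%s' needs '%s' but it was neither produced upstream nor found at %s",
                stage, name, path %||% "<no path configured>"))
}

#' Run the adequacy pipeline
#'
#' Runs the requested stages in dependency order, writing every product as a
#' delimited table under `out_dir` plus a JSON run manifest (package
#' version, seed, row counts). Stages:
#'
#' * `simulate`: generate a synthetic panel and trajectories, written in the
#'   input dialects under `out_dir/inputs/`, and point the remaining stages
#'   at them.
#' * `ingest`: read and merge old/new-era supply tables, population, scheme.
#' * `score`: map commodities to food groups and score every country-year
#'   (`country_supply.csv`, `country_scores.csv`).
#' * `aggregate`: regional supplies, decade summaries with confidence
#'   intervals, total-energy table (`region_supply.csv`,
#'   `region_decade_hdbi.csv`, `region_period_energy.csv`).
#' * `project`: apply scenario trajectories to the base-year supply
#'   (`projection_results.csv`, `projection_summary.csv`).
#' * `report`: write the run manifest (`manifest.json`).
#'
#' A stage whose upstream products are neither in memory (because the
#' upstream stage ran in the same call) nor on disk under the configured
#' paths fails with an error naming the stage.
#'
#' @param config Config list or YAML path; see [load_pipeline_config()].
#' @param stages Subset of
#'   `c("simulate", "ingest", "score", "aggregate", "project", "report")`.
#' @return Invisibly, a list of the tables produced.
#' @export
run_pipeline <- function(config,
                         stages = c("ingest", "score", "aggregate", "report")) {
  all_stages <- c("simulate", "ingest", "score", "aggregate", "project", "report")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]
  config <- load_pipeline_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- list()
  counts <- list()

  if ("simulate" %in% stages) {
    cfg <- do.call(sim_config, c(config$sim %||% list(),
                                 list(seed = config$seed)))
    sim <- simulate_fbs(cfg)
    paths <- write_fbs_fixture(sim, file.path(out_dir, "inputs"))
    traj <- simulate_trajectories(cfg, base_year = config$base_year)
    paths$trajectories <- file.path(out_dir, "inputs", "trajectories.csv")
    readr::write_csv(traj, paths$trajectories)
    readr::write_csv(sim$truth$supply,
                     file.path(out_dir, "inputs", "truth_supply.csv"))
    config$paths <- utils::modifyList(config$paths %||% list(), paths)
    counts$simulated_records <- nrow(sim$records)
  }

  if ("ingest" %in% stages) {
    p <- config$paths
    old <- read_supply_table(p$supply_old, era = "old")
    new <- read_supply_table(p$supply_new, era = "new")
    state$records <- merge_eras(old, new, cutover_year = config$cutover_year)
    if (!is.null(p$population)) {
      state$populations <- read_population(p$population)
    }
    if (!is.null(p$scheme)) {
      state$scheme <- read_region_scheme(
        p$scheme, regions = config$regions %||% unique(readr::read_csv(
          p$scheme, show_col_types = FALSE)$region))
    }
    readr::write_csv(state$records, file.path(out_dir, "merged_records.csv"))
    counts$records <- nrow(state$records)
  }

  if ("score" %in% stages) {
    records <- read_artifact(state, "records",
                             file.path(out_dir, "merged_records.csv"),
                             function(p) readr::read_csv(p, show_col_types = FALSE),
                             "score")
    mapping <- load_mapping(config$paths$mapping)
    targets <- hdb_targets(config$paths$targets)
    state$supply <- group_supply(records, mapping, strict = config$strict)
    state$scores <- score_table(state$supply, targets = targets)
    readr::write_csv(state$supply, file.path(out_dir, "country_supply.csv"))
    readr::write_csv(state$scores, file.path(out_dir, "country_scores.csv"))
    counts$country_years <- nrow(state$scores)
  }

  if ("aggregate" %in% stages) {
    loader <- function(p) readr::read_csv(p, show_col_types = FALSE)
    supply <- read_artifact(state, "supply",
                            file.path(out_dir, "country_supply.csv"),
                            loader, "aggregate")
    scores <- read_artifact(state, "scores",
                            file.path(out_dir, "country_scores.csv"),
                            loader, "aggregate")
    populations <- read_artifact(state, "populations",
                                 config$paths$population, read_population,
                                 "aggregate")
    scheme <- read_artifact(state, "scheme", config$paths$scheme,
                            function(p) read_region_scheme(
                              p, regions = config$regions %||%
                                unique(loader(p)$region)),
                            "aggregate")
    region_sup <- regional_supply(supply, populations, scheme)
    decades <- decade_summary(scores, scheme, decades = config$decades)
    energy <- total_energy(supply, populations, scheme,
                           periods = config$periods %||% hdb_decades()[c(1, 7), ])
    readr::write_csv(region_sup, file.path(out_dir, "region_supply.csv"))
    readr::write_csv(decades, file.path(out_dir, "region_decade_hdbi.csv"))
    readr::write_csv(energy, file.path(out_dir, "region_period_energy.csv"))
    state$scheme <- scheme
    state$supply <- supply
    counts$region_years <- nrow(region_sup)
  }

  if ("project" %in% stages) {
    loader <- function(p) readr::read_csv(p, show_col_types = FALSE)
    supply <- read_artifact(state, "supply",
                            file.path(out_dir, "country_supply.csv"),
                            loader, "project")
    scheme <- read_artifact(state, "scheme", config$paths$scheme,
                            function(p) read_region_scheme(
                              p, regions = config$regions %||%
                                unique(loader(p)$region)),
                            "project")
    traj <- read_artifact(state, "trajectories", config$paths$trajectories,
                          function(p) load_trajectories(p, config$base_year),
                          "project")
    targets <- hdb_targets(config$paths$targets)
    results <- apply_changes(supply, traj, targets = targets,
                             base_year = config$base_year)
    summary <- project_summary(results, scheme)
    readr::write_csv(results, file.path(out_dir, "projection_results.csv"))
    readr::write_csv(summary, file.path(out_dir, "projection_summary.csv"))
    state$projection <- results
    counts$projection_rows <- nrow(results)
  }

  if ("report" %in% stages) {
    manifest <- list(
      package = "hdbindex",
      version = as.character(utils::packageVersion("hdbindex")),
      r_version = R.version.string,
      seed = config$seed,
      stages = stages,
      counts = counts,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(state)
}
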