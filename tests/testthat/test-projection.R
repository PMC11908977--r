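base_supply <- function(entity = "AAA", staples = 1000, fruits = 100,
                        vegetables = 80, asf = 200, legumes = 150, oils = 200,
                        sugar = 150) {
  tibble::tibble(entity = entity, year = 2010L, starchy_staples = staples,
                 fruits = fruits, vegetables = vegetables,
                 animal_source_foods = asf, legumes_nuts_seeds = legumes,
                 oils_fats = oils, sugar_kcal = sugar,
                 total_kcal = staples + fruits + vegetables + asf +
                   legumes + oils + sugar)
}

traj_rows <- function(unit, group, years, delta,
                      scenario = "reference", ssp = "SSP3", rcp = "RCP8.5") {
  tibble::tibble(scenario = scenario, ssp = ssp, rcp = rcp, unit = unit,
                 group = group, year = as.integer(years), delta = delta)
}

test_that("trajectory files validate base year, bounds, and uniqueness", {
  dir <- withr::local_tempdir()
  hdr <- "scenario,ssp,rcp,unit,group,year,delta"
  ok <- file.path(dir, "ok.csv")
  writeLines(c(hdr,
               "reference,SSP3,RCP8.5,AAA,fruits,2010,0",
               "reference,SSP3,RCP8.5,AAA,fruits,2030,0.1",
               "reference,SSP3,RCP8.5,AAA,fruits,2050,0.2"), ok)
  traj <- load_trajectories(ok)
  expect_equal(nrow(traj), 3)

  too_low <- file.path(dir, "low.csv")
  writeLines(c(hdr, "reference,SSP3,RCP8.5,AAA,fruits,2010,0",
               "reference,SSP3,RCP8.5,AAA,fruits,2030,-1.5"), too_low)
  expect_error(load_trajectories(too_low), ">= -1")

  no_base <- file.path(dir, "nobase.csv")
  writeLines(c(hdr, "reference,SSP3,RCP8.5,AAA,fruits,2030,0.1"), no_base)
  expect_error(load_trajectories(no_base), "base year")

  dup <- file.path(dir, "dup.csv")
  writeLines(c(hdr, "reference,SSP3,RCP8.5,AAA,fruits,2010,0",
               "reference,SSP3,RCP8.5,AAA,fruits,2010,0"), dup)
  expect_error(load_trajectories(dup), "duplicate")
})

test_that("zero-delta trajectories reproduce the base exactly at every horizon", {
  base <- base_supply()
  traj <- traj_rows("AAA", rep(hdb_groups(), each = 3),
                    rep(c(2010, 2030, 2050), 6), 0)
  res <- apply_changes(base, traj)
  base_hdbi <- score_table(base)$hdbi
  expect_equal(nrow(res), 3)
  expect_true(all(res$hdbi == base_hdbi))
  for (g in hdb_groups()) expect_true(all(res[[g]] == base[[g]]))
})

test_that("a delta moves only its own group, including the -1 boundary", {
  base <- base_supply()
  traj <- rbind(traj_rows("AAA", "fruits", c(2010, 2050), c(0, 0.10)),
                traj_rows("AAA", "vegetables", c(2010, 2050), c(0, -1)))
  res <- apply_changes(base, traj)
  at50 <- res[res$year == 2050, ]
  expect_equal(at50$fruits, 110)
  expect_equal(at50$vegetables, 0)
  expect_equal(at50$starchy_staples, 1000)
  expect_equal(at50$sugar_kcal, 150) # sugar held at base
  q <- setNames(as.numeric(at50[hdb_groups()]), hdb_groups())
  expect_equal(at50$hdbi, compute_hdbi(q)$hdbi)
})

test_that("raising supply below target helps; above target it is neutral", {
  base <- base_supply() # staples below target (1000 < 1160)
  h0 <- score_table(base)$hdbi
  up <- apply_changes(base, traj_rows("AAA", "starchy_staples",
                                      c(2010, 2050), c(0, 0.10)))
  expect_gt(up$hdbi[up$year == 2050], h0)
  over <- base_supply(staples = 2000) # already above target
  h_over <- score_table(over)$hdbi
  res <- apply_changes(over, traj_rows("AAA", "starchy_staples",
                                       c(2010, 2050), c(0, 0.10)))
  expect_equal(res$hdbi[res$year == 2050], h_over)
})

test_that("chained deltas compound year-on-year growth", {
  base <- base_supply()
  traj <- traj_rows("AAA", "fruits", c(2010, 2020, 2030), c(0, 0.1, 0.1))
  res <- apply_changes(base, traj, chained = TRUE)
  expect_equal(res$fruits[res$year == 2030], 100 * 1.1 * 1.1)
  res_cum <- apply_changes(base, traj)
  expect_equal(res_cum$fruits[res_cum$year == 2030], 110)
})

test_that("country aggregates combine by base-year population weights", {
  members <- base_supply(entity = c("AAA", "BBB"), staples = c(100, 300))
  pop <- tibble::tibble(country_code = c("AAA", "BBB"), year = 2010L,
                        population = c(1e6, 1e6))
  agg <- combine_country_aggregates(members, pop, c("AAA", "BBB"), "BALTICS")
  expect_equal(agg$starchy_staples, 200)

  pop$population <- c(2, 8)
  members$starchy_staples <- c(100, 200)
  members$total_kcal <- NULL
  agg <- combine_country_aggregates(members, pop, c("AAA", "BBB"), "BALTICS")
  expect_equal(agg$starchy_staples, 180) # (2*100 + 8*200)/10

  expect_warning(
    skipped <- combine_country_aggregates(members, pop,
                                          c("AAA", "BBB", "CCC"), "ISLANDS"),
    "CCC")
  expect_null(skipped)
})

test_that("projection and aggregation commute under shared deltas", {
  members <- base_supply(entity = c("AAA", "BBB"),
                         staples = c(900, 1200), fruits = c(60, 140))
  pop <- tibble::tibble(country_code = c("AAA", "BBB"), year = 2010L,
                        population = c(3e6, 7e6))
  traj_one <- function(unit) {
    rbind(traj_rows(unit, "starchy_staples", c(2010, 2050), c(0, 0.2)),
          traj_rows(unit, "fruits", c(2010, 2050), c(0, 0.5)))
  }
  # aggregate then project
  agg <- combine_country_aggregates(members, pop, c("AAA", "BBB"), "AGG")
  path1 <- apply_changes(agg, traj_one("AGG"))
  # project then aggregate (same deltas for both members)
  proj <- apply_changes(members, rbind(traj_one("AAA"), traj_one("BBB")))
  proj50 <- proj[proj$year == 2050, ]
  w <- pop$population / sum(pop$population)
  for (g in hdb_groups()) {
    expect_equal(path1[[g]][path1$year == 2050],
                 sum(w * proj50[[g]]), tolerance = 1e-12)
  }
})

test_that("regional projection summaries are unweighted unit means", {
  base <- base_supply(entity = c("AAA", "BBB"), staples = c(600, 1160))
  traj <- rbind(traj_rows("AAA", "fruits", c(2010, 2050), c(0, 0)),
                traj_rows("BBB", "fruits", c(2010, 2050), c(0, 0)))
  res <- apply_changes(base, traj)
  scheme <- tibble::tibble(country_code = c("AAA", "BBB"), subregion = "X",
                           region = "South Asia")
  summ <- project_summary(res, scheme)
  sa <- summ[summ$region == "South Asia" & summ$year == 2050, ]
  expect_equal(sa$mean_hdbi, mean(res$hdbi[res$year == 2050]))
  expect_equal(sa$n_units, 2L)
  world <- summ[summ$region == "World" & summ$year == 2050, ]
  expect_equal(world$mean_hdbi, sa$mean_hdbi)
})

test_that("investment trajectories dominate reference on shortfall groups", {
  cfg <- tiny_config()
  traj <- simulate_trajectories(cfg)
  sim <- simulate_fbs(cfg)
  sup <- group_supply(sim$records, sim$mapping)
  res <- apply_changes(sup, traj)
  wide <- merge(
    res[res$scenario == "reference", c("unit", "year", "hdbi")],
    res[res$scenario == "increased_investments", c("unit", "year", "hdbi")],
    by = c("unit", "year"), suffixes = c("_ref", "_inv")
  )
  expect_true(all(wide$hdbi_inv >= wide$hdbi_ref - 1e-12))
})
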