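test_that("read_counts parses well-formed rows and rejects bad ones", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "route_id,stratum_id,year,day_of_year,observer_id,first_year,count,valid",
    "r1,s1,2001,150,o1,1,4,1",
    "r2,s1,2001,152,o2,0,0,1"
  ), path)
  recs <- read_counts(path)
  expect_equal(nrow(recs), 2)
  expect_type(recs$count, "integer")
  expect_identical(recs$first_year, c(TRUE, FALSE))

  writeLines(c(
    "route_id,stratum_id,year,day_of_year,observer_id,first_year,count,valid",
    "r1,s1,2001,150,o1,1,-1,1",
    "r2,s1,2001,152,o2,0,3.5,1",
    "r3,s1,2001,400,o3,0,2,1",
    "r4,s1,2001,150,o4,0,5,1"
  ), path)
  expect_warning(recs <- read_counts(path), "rejected")
  expect_equal(nrow(recs), 1)
  expect_equal(recs$route_id, "r4")
  probs <- attr(recs, "problems")
  expect_setequal(probs$row, c(1, 2, 3))
})

test_that("read_counts reports missing columns by name and honors dialects", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("route_id,stratum_id,year,count", "r1,s1,2001,4"), path)
  expect_error(read_counts(path), "day_of_year")

  writeLines(c(
    "Route,Strat,Year,JDay,Obs,FY,SpeciesTotal,RunType",
    "r1,s1,2001,150,o1,0,4,1"
  ), path)
  dialect <- count_dialect(
    route_id = "Route", stratum_id = "Strat", year = "Year",
    day_of_year = "JDay", observer_id = "Obs", first_year = "FY",
    count = "SpeciesTotal", valid = "RunType"
  )
  recs <- read_counts(path, dialect = dialect)
  expect_equal(recs$count, 4L)
  expect_error(count_dialect(nonsense = "x"), "unknown dialect field")
})

test_that("the packaged fixture has the generator's truth structure", {
  dir <- system.file("extdata", "synthetic-run", package = "gamye")
  expect_true(dir.exists(dir))
  ds <- read_dataset(file.path(dir, "counts.csv"), file.path(dir, "strata.csv"))
  expect_equal(dplyr::n_distinct(ds$records$route_id), 6)
  expect_equal(dplyr::n_distinct(ds$records$stratum_id), 2)
  # regenerating with the packaged config reproduces the file byte-for-byte
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cfg <- do.call(sim_config, manifest$config[setdiff(names(manifest$config),
                                                     "seasonal")])
  sim <- simulate_dataset(cfg)
  tmp <- withr::local_tempdir()
  write_simulation(sim, tmp)
  expect_identical(readLines(file.path(tmp, "counts.csv")),
                   readLines(file.path(dir, "counts.csv")))
})

test_that("screen_validity drops invalid runs and out-of-window days", {
  recs <- toy_records(
    list(route_id = "r1", valid = FALSE),
    list(route_id = "r2", day_of_year = 120L),
    list(route_id = "r3", day_of_year = 200L),
    list(route_id = "r4", day_of_year = 145L),
    list(route_id = "r5", day_of_year = 190L)
  )
  kept <- screen_validity(recs, window = c(145, 190))
  expect_setequal(kept$route_id, c("r4", "r5"))
  expect_equal(attr(kept, "dropped"), 3)

  all_good <- toy_records(list(route_id = "r1"), list(route_id = "r2"))
  kept2 <- screen_validity(all_good)
  expect_equal(nrow(kept2), 2)
  expect_equal(attr(kept2, "dropped"), 0)
  expect_error(screen_validity(recs, window = c(190, 145)))
})

test_that("aggregate_stops sums stops per route-year and conserves totals", {
  zeros <- tidyr::expand_grid(route_id = "r1", year = 2001L, stop = 1:50) |>
    dplyr::mutate(count = 0L)
  expect_equal(aggregate_stops(zeros)$count, 0L)

  series <- dplyr::mutate(zeros, count = stop)
  expect_equal(aggregate_stops(series)$count, 1275L)  # sum of 1..50

  grid <- tidyr::expand_grid(route_id = c("r1", "r2"), year = c(2001L, 2002L),
                             stop = 1:5) |>
    dplyr::mutate(count = rpois(dplyr::n(), 3))
  agg <- aggregate_stops(grid)
  expect_equal(nrow(agg), 4)
  expect_equal(sum(agg$count), sum(grid$count))

  dup <- dplyr::bind_rows(grid, grid[1, ])
  expect_error(aggregate_stops(dup), "duplicate \\(route, year, stop\\)")
})

test_that("species_dataset enforces its invariants", {
  recs <- toy_records(list(route_id = "r1"), list(route_id = "r2"))
  strata <- toy_strata("s1")
  ds <- species_dataset(recs, strata, year_range = c(2000, 2010))
  expect_s3_class(ds, "species_dataset")
  expect_error(species_dataset(recs, toy_strata("other"),
                               year_range = c(2000, 2010)),
               "absent from strata")
  expect_error(
    species_dataset(dplyr::bind_rows(recs[1, ], recs[1, ]), strata,
                    year_range = c(2000, 2010)),
    "more than one record per route-year"
  )
  expect_error(read_strata(withr::local_tempfile()), "not found")
})

test_that("inclusion filters keep and drop the intended strata", {
  res <- apply_inclusion_filters(inclusion_toy())
  rep <- res$report
  expect_setequal(unique(res$dataset$records$stratum_id), "pass")
  expect_true(rep$kept[rep$stratum_id == "pass"])
  expect_false(rep$enough_routes[rep$stratum_id == "few_routes"])
  expect_true(rep$enough_years_surveyed[rep$stratum_id == "few_routes"])
  expect_false(rep$enough_years_surveyed[rep$stratum_id == "short_series"])
  expect_true(rep$enough_routes[rep$stratum_id == "short_series"])
  expect_false(rep$enough_years_observed[rep$stratum_id == "sparse_obs"])
  expect_true(rep$enough_routes[rep$stratum_id == "sparse_obs"])
  expect_equal(attr(rep, "routes_kept"), 3)
})

test_that("inclusion filtering is idempotent and order-invariant", {
  ds <- inclusion_toy()
  once <- apply_inclusion_filters(ds)
  twice <- apply_inclusion_filters(once$dataset)
  expect_identical(
    dplyr::arrange(once$dataset$records, route_id, year),
    dplyr::arrange(twice$dataset$records, route_id, year)
  )
  shuffled <- ds
  set.seed(1)
  shuffled$records <- shuffled$records[sample(nrow(shuffled$records)), ]
  res_shuffled <- apply_inclusion_filters(shuffled)
  expect_setequal(res_shuffled$report$stratum_id[res_shuffled$report$kept],
                  once$report$stratum_id[once$report$kept])

  empty <- ds
  empty$records$count <- 0L
  expect_error(apply_inclusion_filters(empty), "no modelable strata")
})
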