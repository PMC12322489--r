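test_that("subsampling keeps the greedy 10-min subset", {
  fx <- make_fixes(seq(0, 20, by = 2), lon = seq(0, 0.2, length.out = 11), lat = 0.5)
  out <- subsample_fixes(fx, 10)
  expect_equal(as.numeric(out$timestamp - fx$timestamp[1], units = "mins"),
               c(0, 10, 20))
  ten <- make_fixes(seq(0, 60, by = 10), lon = 0.5, lat = 0.5)
  expect_identical(subsample_fixes(ten, 10), ten)
  one <- make_fixes(0, lon = 0.5, lat = 0.5)
  expect_identical(subsample_fixes(one, 10), one)
  bad <- make_fixes(c(0, 10, 10), lon = 0.5, lat = 0.5)
  expect_error(subsample_fixes(bad, 10), "strictly increasing")
})

test_that("subsampling never shrinks gaps, reorders or invents fixes", {
  set.seed(3)
  for (i in 1:20) {
    mins <- sort(sample(0:500, 60))
    mins <- mins[!duplicated(mins)]
    fx <- make_fixes(mins, lon = runif(length(mins)), lat = runif(length(mins)))
    out <- subsample_fixes(fx, 10)
    expect_true(all(diff(as.numeric(out$timestamp)) >= 600))
    expect_true(all(out$timestamp %in% fx$timestamp))
    expect_false(is.unsorted(out$timestamp))
  }
})

test_that("trip delineation applies the 200 m / 50 min rules", {
  colony <- c(0.5, 0.5)
  # 6 fixes > 0.2 km spanning 50 min, bracketed by colony fixes
  away_lon <- 0.5 + 0.05 # ~5.5 km away at the equator
  fx <- make_fixes(seq(0, 70, by = 10),
                   lon = c(0.5, rep(away_lon, 6), 0.5),
                   lat = 0.5)
  trips <- delineate_trips(fx, colony)
  expect_length(trips, 1)
  expect_true(trips[[1]]$complete)
  expect_equal(nrow(trips[[1]]$fixes), 6)
  # 5 fixes spanning only 40 min: discarded
  fx40 <- make_fixes(seq(0, 60, by = 10),
                     lon = c(0.5, rep(away_lon, 5), 0.5), lat = 0.5)
  expect_length(delineate_trips(fx40, colony), 0)
  # never leaves the colony radius
  home <- make_fixes(seq(0, 120, by = 10), lon = 0.5, lat = 0.5)
  expect_length(delineate_trips(home, colony), 0)
  expect_length(delineate_trips(home[0, ], colony), 0)
  # exactly 50 minutes qualifies (inclusive rule)
  fx50 <- make_fixes(seq(0, 70, by = 10),
                     lon = c(0.5, rep(away_lon, 6), 0.5), lat = 0.5)
  expect_length(delineate_trips(fx50, colony), 1)
  # run cut by the end of the series is incomplete
  cut <- make_fixes(seq(0, 60, by = 10),
                    lon = c(0.5, rep(away_lon, 6)), lat = 0.5)
  tr <- delineate_trips(cut, colony)
  expect_length(tr, 1)
  expect_false(tr[[1]]$complete)
})

test_that("trip metrics report max range and elapsed duration", {
  colony <- c(0, 0)
  f <- make_fixes(c(0, 10, 20), lon = c(1, 7, 3) * 360 / (2 * pi * 6371),
                  lat = 0)
  m <- trip_metrics(list(fixes = f), colony)
  expect_equal(unname(m["max_range_km"]), 7, tolerance = 1e-6)
  expect_equal(unname(m["duration_h"]), 1 / 3)
  one <- make_fixes(0, lon = 5 * 360 / (2 * pi * 6371), lat = 0)
  m1 <- trip_metrics(list(fixes = one), colony)
  expect_equal(unname(m1["max_range_km"]), 5, tolerance = 1e-6)
  expect_equal(unname(m1["duration_h"]), 0)
})

test_that("land filter is strict at 50% and the return filter at 25%", {
  area <- tiny_area()
  colony <- area$colonies$C1
  mk_trip <- function(n_land, n_sea) {
    make_fixes(seq(0, (n_land + n_sea + 1) * 10, by = 10),
               lon = c(0.5, rep(0.6, n_sea), rep(0.6, n_land), 0.5),
               lat = c(0.5, rep(0.6, n_sea), rep(1.5, n_land), 0.5))
  }
  trips <- make_trips_table(list(mk_trip(6, 4), mk_trip(5, 5), mk_trip(0, 10)),
                            colony, area)
  expect_equal(trips$land_fraction, c(6, 5, 0) / 12, tolerance = 1e-9)
  kept <- exclude_land_trips(trips)
  expect_equal(nrow(kept), 3) # 6/12 = 0.5 is not "more than" half
  trips$land_fraction <- c(0.6, 0.5, 0)
  expect_equal(nrow(exclude_land_trips(trips)), 2)
  expect_equal(exclude_land_trips(trips)$land_fraction, c(0.5, 0))

  # incomplete-trip retention: final fix at exactly 25% of max range stays
  deg <- function(km) km * 360 / (2 * pi * 6371)
  mk_return <- function(last_km, max_km = 100) {
    # along a meridian the distance is exactly proportional to the offset
    make_fixes(seq(0, 50, by = 10), lon = 0.5,
               lat = 0.5 + deg(c(10, 50, max_km, 60, 30, last_km)))
  }
  tt <- make_trips_table(list(mk_return(25), mk_return(10), mk_return(80),
                              mk_return(80)),
                         colony, area, complete = c(FALSE, FALSE, FALSE, TRUE))
  kept <- filter_incomplete(tt, area)
  expect_equal(kept$trip_index, c(1, 2, 4)) # 25 <= 25 kept; 10 kept; 80 dropped;
  # complete trip with a far last fix always kept
})

test_that("the two trip filters commute", {
  st <- default_study()
  raw <- segment_trips(st$fixes, st$deployments, st$area)
  a <- filter_incomplete(exclude_land_trips(raw), st$area)
  b <- exclude_land_trips(filter_incomplete(raw, st$area))
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("per-individual range uses the first deployment only", {
  area <- tiny_area()
  colony <- area$colonies$C1
  deg <- function(km) km * 360 / (2 * pi * 6371)
  t0 <- as.POSIXct("2018-07-01 00:00:00", tz = "UTC")
  mk <- function(km, start_h) {
    make_fixes(start_h * 60 + seq(0, 60, by = 10), lon = 0.5, lat = 0.5 + deg(km))
  }
  trips <- make_trips_table(list(mk(5.2, 0), mk(118, 5), mk(300, 48)), colony, area)
  trips$dep_id <- c(1, 1, 2) # second deployment reaches farther
  imr <- individual_max_range(trips)
  expect_equal(nrow(imr), 1)
  expect_equal(imr$max_range_km, 118, tolerance = 1e-3)
  imr_all <- individual_max_range(trips, first_deployment_only = FALSE)
  expect_equal(imr_all$max_range_km, 300, tolerance = 1e-2)
})

test_that("retained trips always exceed the colony radius", {
  st <- default_study()
  trips <- segmented_trips(st)
  expect_true(all(trips$max_range_km > 0.2))
  expect_true(all(trips$land_fraction >= 0 & trips$land_fraction <= 1))
})

test_that("trip tables round-trip through CSV", {
  st <- default_study()
  trips <- segmented_trips(st)
  path <- tempfile(fileext = ".csv")
  write_trips_csv(trips, path)
  back <- read_trips_csv(path)
  expect_equal(nrow(back), nrow(trips))
  expect_equal(back$max_range_km, trips$max_range_km)
  expect_equal(back$start, trips$start)
})
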