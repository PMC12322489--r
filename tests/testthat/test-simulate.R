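test_that("identical configuration and seed reproduce the study exactly", {
  cfg <- sim_config()
  a <- simulate_study(cfg, seed = 33)
  b <- simulate_study(cfg, seed = 33)
  expect_identical(a$fixes, b$fixes)
  expect_identical(a$morpho, b$morpho)
  expect_identical(a$net_samples, b$net_samples)
  expect_identical(a$ground_truth$trips, b$ground_truth$trips)
  c2 <- simulate_study(cfg, seed = 34)
  expect_false(identical(a$fixes, c2$fixes))
})

test_that("ground-truth labels agree with geometric classification", {
  st <- clean_study()
  raw <- segment_trips(st$fixes, st$deployments, st$area)
  gt <- st$ground_truth$trips
  m <- merge(gt, as.data.frame(raw), by = c("bird_id", "trip_index"))
  expect_equal(nrow(m), nrow(gt))
  expect_identical(m$type == "outside", m$label == "outside")
})

test_that("outside-trip extremes are honoured", {
  cfg0 <- sim_config(p_outside = c(0, 0, 0), battery_failure_prob = 0,
                     land_excursion_prob = 0)
  st0 <- simulate_study(cfg0, seed = 35)
  expect_true(all(st0$ground_truth$trips$type == "inside"))
  cfg1 <- sim_config(p_outside = c(1, 1, 1), battery_failure_prob = 0,
                     land_excursion_prob = 0)
  st1 <- simulate_study(cfg1, seed = 35)
  expect_true(all(st1$ground_truth$trips$type == "outside"))
})

test_that("the trip-level outside fraction matches the configured probability", {
  # many birds so the binomial error is small; heterogeneity is centred,
  # so the trip-level mean must still be ~0.31
  cfg <- sim_config(n_birds = list(OBS = c(0L, 0L, 350L), OSS = c(0L, 0L, 350L)),
                    battery_failure_prob = 0, land_excursion_prob = 0)
  st <- simulate_study(cfg, seed = 36)
  gt <- st$ground_truth$trips
  frac <- mean(gt$type == "outside")
  expect_gt(nrow(gt), 2500)
  expect_lt(abs(frac - 0.31), 0.025)
})

test_that("trip counts stay in the configured range and masses follow the models", {
  st <- default_study()
  gt <- st$ground_truth$birds
  expect_true(all(gt$n_trips >= 1 & gt$n_trips <= 16))
  expect_equal(nrow(st$morpho), 78) # bird-season numbers of the emulated design
  # no mass dynamics: recapture equals capture exactly
  cfg0 <- sim_config(bmc_prop_slope = 0, bmc_year_levels = c(0, 0, 0),
                     bmc_colony_effect = 0, bmc_resid_sd = 0, bmc_bird_sd = 0)
  st0 <- simulate_study(cfg0, seed = 37)
  expect_equal(st0$morpho$mass_recapture_g, st0$morpho$mass_capture_g)
  # mass-change responds to the proportion slope
  st1 <- default_study()
  b <- st1$ground_truth$birds
  bmc_obs <- relative_body_mass_change(st1$morpho$mass_capture_g,
                                       st1$morpho$mass_recapture_g)
  expect_gt(cor(b$prop_outside_true, bmc_obs), 0.1)
})

test_that("range and duration are strongly correlated across trips", {
  st <- clean_study()
  raw <- segment_trips(st$fixes, st$deployments, st$area)
  r <- cor(raw$max_range_km, raw$duration_h)
  expect_gt(r, 0.6)
})

test_that("a 2018-like season is bimodal and a 2016-like one is not", {
  # distributional check across a handful of seeds (dip on the
  # per-individual maxima after full segmentation)
  p18 <- p16 <- numeric(5)
  for (s in 1:5) {
    st <- simulate_study(sim_config(), seed = 400 + s)
    trips <- filter_incomplete(exclude_land_trips(
      segment_trips(st$fixes, st$deployments, st$area)), st$area)
    imr <- individual_max_range(trips)
    v18 <- imr$max_range_km[imr$year == 2018]
    v16 <- imr$max_range_km[imr$year == 2016]
    p18[s] <- dip_pvalue(dip_statistic(v18), length(v18), 999, 5)$p_value
    p16[s] <- dip_pvalue(dip_statistic(v16), length(v16), 999, 5)$p_value
  }
  expect_gte(mean(p18 < 0.05), 0.8)
  expect_lte(mean(p16 < 0.05), 0.2)
})

test_that("studies serialise to plain-text files and back", {
  st <- clean_study()
  dir <- tempfile()
  write_study(st, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "fixes.csv", "deployments.csv", "morpho.csv", "net_samples.csv",
    "dry_mass.csv", "area.geojson", "ground_truth.json")))))
  fx <- read.csv(file.path(dir, "fixes.csv"))
  expect_equal(nrow(fx), nrow(st$fixes))
  area <- read_study_area(file.path(dir, "area.geojson"))
  expect_equal(sort(names(area$colonies)), c("OBS", "OSS"))
  unlink(dir, recursive = TRUE)
})
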