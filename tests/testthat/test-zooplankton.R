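mk_samples <- function(ab_by_stratum, species = "sp1") {
  do.call(rbind, lapply(seq_along(ab_by_stratum), function(i) {
    data.frame(station_id = "st1", top_depth_m = (i - 1) * 50,
               bottom_depth_m = i * 50, species_id = species,
               abundance_ind_m3 = ab_by_stratum[i], stringsAsFactors = FALSE)
  }))
}

test_that("station biomass is strata-averaged abundance times dry mass", {
  dm <- data.frame(species_id = c("sp1", "sp2"), dry_mass_mg = c(1, 2))
  expect_equal(station_biomass(mk_samples(c(2, 2, 2)), dm), 2)
  expect_equal(station_biomass(mk_samples(c(1, 3)), dm <- data.frame(
    species_id = "sp1", dry_mass_mg = 2)), 4)
  # linearity: doubling one species doubles only its contribution
  dm2 <- data.frame(species_id = c("sp1", "sp2"), dry_mass_mg = c(1, 2))
  two_sp <- rbind(mk_samples(c(1, 3), "sp1"), mk_samples(c(2, 2), "sp2"))
  base <- station_biomass(two_sp, dm2)
  doubled <- two_sp
  doubled$abundance_ind_m3[doubled$species_id == "sp1"] <-
    2 * doubled$abundance_ind_m3[doubled$species_id == "sp1"]
  expect_equal(station_biomass(doubled, dm2) - base, mean(c(1, 3)) * 1)
  expect_error(station_biomass(mk_samples(c(1, 2), "mystery"), dm2), "mystery")
  # thickness weighting changes uneven strata
  uneven <- mk_samples(c(10, 0))
  uneven$bottom_depth_m <- c(10, 300)
  uneven$top_depth_m <- c(0, 10)
  dm1 <- data.frame(species_id = "sp1", dry_mass_mg = 1)
  expect_equal(station_biomass(uneven, dm1), 5)
  expect_equal(station_biomass(uneven, dm1, weight_by_thickness = TRUE),
               10 * 10 / 300)
})

test_that("yearly index is the station mean with a percentile bootstrap", {
  idx <- yearly_index(c(2, 4, 6, 8, 10), n_boot = 999, seed = 4)
  expect_equal(idx$index, 6)
  expect_gte(idx$ci_low, 2)
  expect_lte(idx$ci_high, 10)
  same <- yearly_index(rep(3.3, 5), n_boot = 199, seed = 4)
  expect_equal(c(same$ci_low, same$ci_high), c(3.3, 3.3))
  # permutation invariance of stations
  idx2 <- yearly_index(c(10, 8, 6, 4, 2), n_boot = 999, seed = 4)
  expect_equal(idx2$index, idx$index)
  expect_error(yearly_index(numeric(0)), "stations")
})

test_that("scaling all abundances scales index and interval linearly", {
  st <- default_study()
  bm <- biomass_by_year(st$net_samples, st$dry_mass, n_boot = 299, seed = 6)
  scaled <- st$net_samples
  scaled$abundance_ind_m3 <- 3 * scaled$abundance_ind_m3
  bm3 <- biomass_by_year(scaled, st$dry_mass, n_boot = 299, seed = 6)
  for (y in names(bm)) {
    expect_equal(bm3[[y]]$index, 3 * bm[[y]]$index, tolerance = 1e-9)
    expect_equal(bm3[[y]]$ci_low, 3 * bm[[y]]$ci_low, tolerance = 1e-9)
  }
})

test_that("the synthetic years order their biomass as configured", {
  st <- default_study()
  bm <- biomass_by_year(st$net_samples, st$dry_mass, n_boot = 199, seed = 6)
  idx <- vapply(bm, function(b) b$index, numeric(1))
  # 2018 configured as the poorest season
  expect_lt(idx[["2018"]], idx[["2016"]])
  expect_lt(idx[["2018"]], idx[["2017"]])
})
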