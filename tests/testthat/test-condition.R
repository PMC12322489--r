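test_that("morphometric sex cutoff treats 90.5 mm as female", {
  expect_identical(sex_from_headbill(89.0), "female")
  expect_identical(sex_from_headbill(92.0), "male")
  expect_identical(sex_from_headbill(90.5), "female")
  expect_identical(sex_from_headbill(c(88, 91)), c("female", "male"))
  expect_error(sex_from_headbill(-3), "positive")
})

test_that("body condition is the OLS residual of mass on head-bill", {
  set.seed(10)
  hb <- rnorm(60, 90.5, 2.5)
  mass <- -169 + 5.96 * hb + rnorm(60, 0, 30)
  rec <- data.frame(head_bill_mm = hb, mass_capture_g = mass)
  bc <- body_condition(rec)
  expect_equal(sum(bc$bc), 0, tolerance = 1e-6)
  ci <- attr(bc, "slope_ci")
  expect_true(ci[1] < 5.96 && 5.96 < ci[2])
  # shifting every mass shifts the intercept, not the residuals
  rec2 <- rec
  rec2$mass_capture_g <- rec2$mass_capture_g + 250
  bc2 <- body_condition(rec2)
  expect_equal(bc2$bc, bc$bc, tolerance = 1e-9)
  expect_equal(attr(bc2, "intercept"), attr(bc, "intercept") + 250, tolerance = 1e-6)
  expect_error(body_condition(data.frame(head_bill_mm = rep(90, 5),
                                         mass_capture_g = rnorm(5, 370, 10))),
               "zero variance")
})

test_that("condition regression recovers the generating slope on synthetic birds", {
  st <- default_study()
  bc <- body_condition(st$morpho)
  ci <- attr(bc, "slope_ci")
  expect_true(ci[1] < 5.96 && 5.96 < ci[2])
})

test_that("relative body-mass change is the signed proportion", {
  expect_equal(relative_body_mass_change(400, 380), -0.05)
  expect_equal(relative_body_mass_change(415, 415), 0)
  expect_equal(relative_body_mass_change(360, 396), 0.10)
  expect_true(is.na(relative_body_mass_change(400, NA)))
  expect_error(relative_body_mass_change(0, 10), "positive")
})

test_that("weighted proportion equals the pooled trips ratio exactly", {
  wp <- weighted_outside_proportion(c(1, 0), c(2, 8), n_boot = 99, seed = 1)
  expect_equal(wp$estimate, 0.2)
  # equal weights reduce to the simple mean
  p <- c(0.2, 0.6, 0.1)
  expect_equal(weighted_outside_proportion(p, c(3, 3, 3), n_boot = 99, seed = 1)$estimate,
               mean(p))
  z <- weighted_outside_proportion(rep(0, 5), c(2, 3, 1, 4, 2), n_boot = 199, seed = 1)
  expect_equal(z$estimate, 0)
  expect_equal(c(z$ci_low, z$ci_high), c(0, 0))
  expect_error(weighted_outside_proportion(c(0, 1), c(0, 0)), "weights")
})

test_that("bootstrap interval brackets the estimate on non-degenerate data", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(8:40, 1)
    w <- sample(1:16, n, replace = TRUE)
    p <- rbinom(n, w, 0.3) / w
    wp <- weighted_outside_proportion(p, w, n_boot = 499, seed = i)
    expect_true(wp$ci_low <= wp$estimate + 1e-9)
    expect_true(wp$ci_high >= wp$estimate - 1e-9)
  }
})

test_that("condition table joins trips, sexes and metrics per bird", {
  st <- default_study()
  trips <- segmented_trips(st)
  ct <- condition_table(st$morpho, trips)
  expect_true(all(c("sex", "bc", "bmc", "prop_outside", "first_outside") %in% names(ct)))
  expect_true(all(ct$sex %in% c("female", "male")))
  with_trips <- ct[!is.na(ct$n_trips), ]
  expect_true(all(with_trips$n_outside <= with_trips$n_trips))
  expect_true(all(with_trips$prop_outside >= 0 & with_trips$prop_outside <= 1))
  # molecular sex overrides the cutoff when present
  known <- ct[!is.na(st$morpho$sex_molecular[match(ct$bird_id, st$morpho$bird_id)]), ]
  expect_equal(known$sex,
               st$morpho$sex_molecular[match(known$bird_id, st$morpho$bird_id)])
})
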