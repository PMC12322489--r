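test_that("design matrices encode the printed model structures", {
  dat <- data.frame(bird_id = c("a", "a", "b", "c", "d", "d", "e", "f"),
                    year = c(2016, 2018, 2017, 2016, 2017, 2018, 2016, 2018),
                    colony_id = c("OBS", "OBS", "OSS", "OSS", "OBS", "OSS", "OBS", "OSS"),
                    max_range_km = c(5, 120, 8, 6, 7, 90, 5, 110),
                    label = c("inside", "outside", "inside", "inside",
                              "inside", "outside", "inside", "outside"))
  d1 <- build_design("M1_logrange", dat)
  expect_equal(colnames(d1$X), c("(Intercept)", "year2017", "year2018", "colonyOSS"))
  # reference cell: only the intercept active
  expect_equal(unname(d1$X[1, ]), c(1, 0, 0, 0))
  expect_equal(unname(d1$X[2, ]), c(1, 0, 1, 0))
  expect_equal(unname(d1$X[3, ]), c(1, 1, 0, 1))
  expect_equal(d1$y, log(dat$max_range_km))
  expect_equal(d1$grp, c(1, 1, 2, 3, 4, 4, 5, 6))

  cond <- data.frame(bird_id = letters[1:12], year = rep(c(2016, 2017, 2018), 4),
                     colony_id = rep(c("OBS", "OSS"), each = 6),
                     bc = rnorm(12), prop_outside = runif(12), bmc = rnorm(12, 0, .05),
                     first_outside = sample(c("inside", "outside"), 12, replace = TRUE))
  d4 <- build_design("M4_bmc", cond)
  # cell-means year coding: no global intercept, one indicator per year
  expect_equal(colnames(d4$X), c("prop", "I.year2016", "I.year2017", "I.year2018", "colonyOSS"))
  expect_true(all(rowSums(d4$X[, 2:4]) == 1))
  r <- d4$X[which(cond$year == 2017 & cond$colony_id == "OBS")[1], ]
  expect_equal(unname(r[-1]), c(0, 1, 0, 0))
  expect_error(build_design("M1_logrange", dat[1, ]), "too few")
})

test_that("gaussian fits with negligible grouping match least squares", {
  set.seed(16)
  n <- 150
  dat <- data.frame(bird_id = paste0("b", seq_len(n)), # one row per bird: no RE info
                    year = sample(c(2016, 2017, 2018), n, replace = TRUE),
                    colony_id = sample(c("OBS", "OSS"), n, replace = TRUE))
  eta <- 1.6 + 0.4 * (dat$year == 2017) - 0.3 * (dat$year == 2018) +
    0.2 * (dat$colony_id == "OSS")
  dat$max_range_km <- exp(eta + rnorm(n, 0, 0.5))
  dat$label <- "inside"
  fit <- fit_model("M1_logrange", dat, chains = 3, iterations = 2500,
                   warmup = 1000, seed = 21)
  s <- fit_summary(fit, neff_min = 300)$table
  ols <- lm(log(max_range_km) ~ factor(year) + factor(colony_id), dat)
  co <- coef(ols)
  for (j in 1:4) {
    post_sd <- (s$pi_high[j] - s$pi_low[j]) / (2 * 1.96)
    expect_lt(abs(s$mean[j] - co[j]), 2 * post_sd + 0.02)
  }
})

test_that("logit fits with no random-effect structure match logistic regression", {
  set.seed(17)
  n <- 400
  dat <- data.frame(bird_id = paste0("b", seq_len(n)),
                    year = sample(c(2016, 2017, 2018), n, replace = TRUE),
                    colony_id = sample(c("OBS", "OSS"), n, replace = TRUE))
  eta <- -1.5 + 1.2 * (dat$year == 2018) + 0.5 * (dat$colony_id == "OSS")
  dat$label <- ifelse(runif(n) < plogis(eta), "outside", "inside")
  fit <- fit_model("M2_outside", dat, chains = 3, iterations = 2500,
                   warmup = 1000, seed = 22)
  s <- fit_summary(fit, neff_min = 300)$table
  glm_fit <- glm(I(label == "outside") ~ factor(year) + factor(colony_id),
                 binomial(), dat)
  co <- coef(glm_fit)
  se <- sqrt(diag(vcov(glm_fit)))
  for (j in 1:4) {
    expect_lt(abs(s$mean[j] - co[j]), 2 * (s$pi_high[j] - s$pi_low[j]) / (2 * 1.96) +
                0.5 * se[j])
  }
})

test_that("back-transformation returns lognormal medians", {
  st <- default_study()
  trips <- segmented_trips(st)
  inside <- trips[trips$label == "inside", ]
  fit <- fit_model("M1_logrange", inside, chains = 2, iterations = 1200,
                   warmup = 600, seed = 23)
  bt <- backtransform_median(fit, year = 2016, colony_id = "OBS")
  # reference-cell median must sit near the generating inside median
  expect_lt(abs(bt$median - 5.2) / 5.2, 0.35)
  expect_true(bt$pi_low < bt$median && bt$median < bt$pi_high)
  # adding +c to all draws multiplies the median by exp(c)
  fit2 <- fit
  i_int <- match("(Intercept)", fit$par_names)
  fit2$draws[, i_int, ] <- fit2$draws[, i_int, ] + 0.7
  bt2 <- backtransform_median(fit2, year = 2016, colony_id = "OBS")
  expect_equal(bt2$median, bt$median * exp(0.7), tolerance = 1e-9)
  expect_error(backtransform_median(
    fit_model("M2_outside", trips, chains = 2, iterations = 400, warmup = 200, seed = 1),
    year = 2016, colony_id = "OBS"), "gaussian")
})

test_that("contrasts measure response-scale differences with an evidence flag", {
  st <- default_study()
  trips <- segmented_trips(st)
  fit <- fit_model("M1_logrange", trips, chains = 2, iterations = 1200,
                   warmup = 600, seed = 24)
  same <- contrast_cells(fit, list(year = 2017, colony_id = "OBS"),
                         list(year = 2017, colony_id = "OBS"))
  expect_equal(same$mean, 0)
  expect_false(same$evidence)
  # outside vs inside medians generated ~70+ km apart in 2016
  d16 <- local({
    inside <- fit_model("M1_logrange", trips[trips$label == "inside", ],
                        chains = 2, iterations = 1200, warmup = 600, seed = 25)
    outside <- fit_model("M1_logrange", trips[trips$label == "outside", ],
                         chains = 2, iterations = 1200, warmup = 600, seed = 26)
    backtransform_median(outside, 2016, "OBS")$median -
      backtransform_median(inside, 2016, "OBS")$median
  })
  expect_gt(d16, 20)
})

test_that("posterior predictive checks accept self-generated data", {
  st <- default_study()
  trips <- segmented_trips(st)
  fit <- fit_model("M1_logrange", trips[trips$label == "inside", ],
                   chains = 2, iterations = 1500, warmup = 700, seed = 27)
  ppc <- posterior_predictive_check(fit, n_rep = 150, seed = 5)
  expect_true(all(c("mean", "sd") %in% ppc$statistic))
  ok <- ppc$p_lower >= 0.05 & ppc$p_lower <= 0.95
  expect_gte(mean(ok[ppc$statistic %in% c("mean", "sd")]), 0.5)
  # constant response must flag the sd summary as unreproducible
  dat <- trips[trips$label == "inside", ]
  dat$max_range_km <- 5.0
  fitc <- fit_model("M1_logrange", dat, chains = 2, iterations = 800,
                    warmup = 400, seed = 28)
  ppc_c <- posterior_predictive_check(fitc, n_rep = 100, seed = 5)
  p_sd <- ppc_c$p_lower[ppc_c$statistic == "sd"]
  expect_true(p_sd < 0.05 || p_sd > 0.95)
})

test_that("recoding the reference year leaves fitted cell means unchanged", {
  st <- default_study()
  trips <- segmented_trips(st)
  inside <- trips[trips$label == "inside", ]
  f_a <- fit_model(model_spec("M1_logrange", ref_year = 2016), inside,
                   chains = 2, iterations = 1500, warmup = 700, seed = 29)
  f_b <- fit_model(model_spec("M1_logrange", ref_year = 2017), inside,
                   chains = 2, iterations = 1500, warmup = 700, seed = 30)
  for (yr in c(2016, 2017, 2018)) {
    m_a <- backtransform_median(f_a, yr, "OBS")$median
    m_b <- backtransform_median(f_b, yr, "OBS")$median
    expect_lt(abs(log(m_a / m_b)), 0.05)
  }
})
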