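#' Synthetic study area
#'
#' A rectangular fjord of roughly 230 km^2 at high latitude with two
#' colonies in its inner half, land strips along the north and south
#' shores, and open sea beyond the western mouth. The geometry is not a
#' real coastline; it exists to exercise every segmentation and
#' classification rule (colony-distance runs, land overlap,
#' inside/outside labels).
#'
#' @return A \code{cpf_study_area} with colonies \code{"OBS"} and
#'   \code{"OSS"}.
#' @export
synthetic_study_area <- function() {
  fjord <- cbind(lon = c(11.10, 12.18, 12.18, 11.10, 11.10),
                 lat = c(78.88, 78.88, 78.97, 78.97, 78.88))
  land_north <- cbind(lon = c(11.10, 12.30, 12.30, 11.10, 11.10),
                      lat = c(78.97, 78.97, 79.04, 79.04, 78.97))
  land_south <- cbind(lon = c(11.10, 12.30, 12.30, 11.10, 11.10),
                      lat = c(78.81, 78.81, 78.88, 78.88, 78.81))
  land_east <- cbind(lon = c(12.18, 12.30, 12.30, 12.18, 12.18),
                     lat = c(78.88, 78.88, 78.97, 78.97, 78.88))
  study_area(fjord,
             land = list(land_north, land_south, land_east),
             colonies = list(OBS = c(11.70, 78.935), OSS = c(11.78, 78.915)))
}

#' Simulation configuration
#'
#' Defaults describe a three-season, two-colony tracking study: bird
#' numbers per colony and season follow the study design being emulated;
#' trip counts are a discretised normal (mean 5.3, sd 3.3) clipped to
#' [1, 16]; the yearly outside-trip probabilities (7\%, 2\%, 31\%) and
#' the inside/outside range medians (5.2/6.7/5.6 and 75.1/23.3/90.2 km)
#' are the observed yearly values used as generating truth; body-mass
#' dynamics follow the mass-change linear model (proportion slope 0.054,
#' yearly levels -2.1\%/-7.9\%/-3.4\%, residual sd 0.04, bird sd 0.01)
#' and the condition regression (5.96 g/mm). Log-scale spreads, flight
#' speed and foraging-bout durations are generator choices documented in
#' the methods vignette.
#'
#' @param years Study years.
#' @param n_birds Named list per colony of per-year bird counts.
#' @param trips_per_bird_mean,trips_per_bird_sd,trips_range Trip-count
#'   distribution.
#' @param fix_interval_min GPS fix cadence in minutes (2-10).
#' @param p_outside Named per-year outside-trip probability.
#' @param inside_median_km,inside_log_sd Inside-fjord trip range
#'   lognormal parameters (per-year medians).
#' @param outside_median_km,outside_log_sd Outside-fjord equivalents.
#' @param bird_range_sd_log Bird random intercept sd on the log-range
#'   scale.
#' @param bird_logit_sd Bird random intercept sd on the logit
#'   outside-propensity scale.
#' @param flight_speed_kmh Commuting speed.
#' @param battery_failure_prob Probability a deployment's tail is lost
#'   (0.5 makes roughly 8\% of trips incomplete, the rate the emulated
#'   study reports).
#' @param land_excursion_prob Probability a trip is a land excursion
#'   (bathing/nest material; >50\% of fixes on land).
#' @param condition_slope,condition_intercept,condition_resid_sd Mass ~
#'   head-bill regression used to generate capture masses.
#' @param headbill_female_mean,headbill_male_mean,headbill_sd Sex-specific
#'   head-bill distributions around the 90.5 mm cutoff.
#' @param molecular_sex_prob Fraction of birds with molecular sex
#'   available.
#' @param bmc_prop_slope,bmc_year_levels,bmc_colony_effect,bmc_resid_sd,bmc_bird_sd
#'   Mass-change model used to generate recapture masses.
#' @param zoo_year_scale Per-year multiplier on zooplankton abundances.
#' @return List of class \code{cpf_sim_config}.
#' @export
sim_config <- function(
    years = c(2016L, 2017L, 2018L),
    n_birds = list(OBS = c(20L, 13L, 9L), OSS = c(16L, 8L, 12L)),
    trips_per_bird_mean = 5.3, trips_per_bird_sd = 3.3, trips_range = c(1L, 16L),
    fix_interval_min = 10,
    p_outside = c(0.07, 0.02, 0.31),
    inside_median_km = c(5.2, 6.7, 5.6), inside_log_sd = 0.35,
    outside_median_km = c(75.1, 23.3, 90.2), outside_log_sd = c(0.55, 0.55, 0.15),
    bird_range_sd_log = 0.10, bird_logit_sd = 2.5,
    flight_speed_kmh = 35,
    battery_failure_prob = 0.45,
    land_excursion_prob = 0.05,
    condition_slope = 5.96, condition_intercept = -169,
    condition_resid_sd = 33,
    headbill_female_mean = 88.5, headbill_male_mean = 93.0, headbill_sd = 1.3,
    molecular_sex_prob = 0.94,
    bmc_prop_slope = 0.054,
    bmc_year_levels = c(-0.021, -0.079, -0.034),
    bmc_colony_effect = 0.0,
    bmc_resid_sd = 0.04, bmc_bird_sd = 0.01,
    zoo_year_scale = c(1.6, 1.15, 0.45)) {
  cfg <- as.list(environment())
  names(cfg$p_outside) <- names(cfg$inside_median_km) <-
    names(cfg$outside_median_km) <- names(cfg$outside_log_sd) <-
    names(cfg$bmc_year_levels) <- names(cfg$zoo_year_scale) <- as.character(years)
  stopifnot(all(cfg$p_outside >= 0 & cfg$p_outside <= 1),
            cfg$fix_interval_min >= 2, cfg$fix_interval_min <= 10)
  class(cfg) <- "cpf_sim_config"
  cfg
}

# intercept of the centred logit-normal outside-propensity: chosen so the
# population mean trip-level outside probability equals the target p even
# under strong bird-level heterogeneity
.center_logit <- function(p, sd) {
  if (p <= 0) return(-Inf)
  if (p >= 1) return(Inf)
  if (sd == 0) return(stats::qlogis(p))
  zs <- seq(-6, 6, length.out = 201)
  w <- stats::dnorm(zs)
  w <- w / sum(w)
  stats::uniroot(function(a) sum(w * stats::plogis(a + sd * zs)) - p,
                 c(-40, 20))$root
}

# distance from a colony to the fjord ring along a bearing (km), by
# bisection on the destination point; the rectangle guarantees a single
# crossing
.ray_to_ring <- function(colony, bearing, area, max_km = 40) {
  inside_at <- function(d) {
    p <- destination_point(colony[1], colony[2], bearing, d)
    point_in_polygon(p[1], p[2], area$fjord)
  }
  if (inside_at(max_km)) return(max_km)
  lo <- 0
  hi <- max_km
  while (hi - lo > 0.05) {
    mid <- (lo + hi) / 2
    if (inside_at(mid)) lo <- mid else hi <- mid
  }
  lo
}

# Render one out-and-back trip as fixes on the dt grid: distance profile
# d(t) = min(v t, range, v (T - t)) along a fixed bearing, T a multiple
# of dt. Returns lon/lat matrix including the colony fixes at both ends.
.render_track <- function(colony, bearing, range_km, duration_h, speed, dt_min) {
  dt_h <- dt_min / 60
  T_h <- max(ceiling(duration_h / dt_h), 3) * dt_h
  tt <- seq(0, T_h, by = dt_h)
  d <- pmin(pmin(speed * tt, range_km), speed * (T_h - tt))
  d[d < 0] <- 0
  pos <- t(vapply(d, function(di) {
    if (di <= 0) c(colony[1], colony[2]) else
      destination_point(colony[1], colony[2], bearing, di)
  }, numeric(2)))
  list(t_h = tt, lon = pos[, 1], lat = pos[, 2], T_h = T_h)
}

#' Simulate a complete synthetic study
#'
#' Generates GPS fixes, deployments, morphometrics and zooplankton net
#' samples with the statistical structure the analysis pipeline assumes:
#' out-and-back trips from two colonies with year-specific mixtures of
#' short inside-fjord and long outside-fjord trips, bird-level random
#' intercepts on both the log range and the logit outside-propensity,
#' optional land excursions and battery-failure truncation, and body
#' masses generated from the condition regression and the mass-change
#' model. Identical configuration and seed give identical output.
#'
#' @param config A \code{cpf_sim_config}.
#' @param seed Integer seed.
#' @return List of class \code{cpf_study}: \code{fixes},
#'   \code{deployments}, \code{morpho}, \code{net_samples} (data
#'   frames), \code{area} (study area), \code{ground_truth} (list with
#'   per-trip and per-bird truth and the generating coefficients).
#' @export
simulate_study <- function(config = sim_config(), seed = 1) {
  area <- synthetic_study_area()
  with_seed(seed, .simulate_study_impl(config, area))
}

.simulate_study_impl <- function(cfg, area) {
  years <- cfg$years
  dt <- cfg$fix_interval_min
  speed <- cfg$flight_speed_kmh
  fixes <- list()
  deployments <- list()
  gt_trips <- list()
  gt_birds <- list()
  morpho <- list()
  bird_no <- 0

  for (colony_id in names(cfg$n_birds)) {
    colony <- area$colonies[[colony_id]]
    # angular window of the fjord mouth as seen from the colony
    mouth_lat <- c(78.885, 78.965)
    west_bearings <- vapply(mouth_lat, function(la) {
      p <- c(11.105, la)
      (atan2(sin((p[1] - colony[1]) * pi / 180) * cos(p[2] * pi / 180),
             cos(colony[2] * pi / 180) * sin(p[2] * pi / 180) -
               sin(colony[2] * pi / 180) * cos(p[2] * pi / 180) *
                 cos((p[1] - colony[1]) * pi / 180)) * 180 / pi) %% 360
    }, numeric(1))
    for (yi in seq_along(years)) {
      yr <- years[yi]
      ykey <- as.character(yr)
      alpha_out <- .center_logit(cfg$p_outside[ykey], cfg$bird_logit_sd)
      for (b in seq_len(cfg$n_birds[[colony_id]][yi])) {
        bird_no <- bird_no + 1
        bird_id <- sprintf("bird%03d", bird_no)
        b_range <- stats::rnorm(1, 0, cfg$bird_range_sd_log)
        b_out <- stats::rnorm(1, 0, cfg$bird_logit_sd)
        n_trips <- round(stats::rnorm(1, cfg$trips_per_bird_mean, cfg$trips_per_bird_sd))
        n_trips <- min(max(n_trips, cfg$trips_range[1]), cfg$trips_range[2])

        capture <- as.POSIXct(sprintf("%d-07-%02d 09:00:00", yr,
                                      sample(3:20, 1)), tz = "UTC") +
          round(stats::runif(1, 0, 120)) * 60
        t_cursor <- 0 # hours since capture
        bird_fix_t <- numeric(0)
        bird_fix_lon <- numeric(0)
        bird_fix_lat <- numeric(0)
        add_colony_fixes <- function(from_h, to_h) {
          if (to_h <= from_h) return(invisible(NULL))
          tt <- seq(from_h, to_h - dt / 60, by = dt / 60)
          bird_fix_t <<- c(bird_fix_t, tt)
          bird_fix_lon <<- c(bird_fix_lon, rep(colony[1], length(tt)))
          bird_fix_lat <<- c(bird_fix_lat, rep(colony[2], length(tt)))
        }

        for (k in seq_len(n_trips)) {
          gap_h <- exp(stats::rnorm(1, log(1.5), 0.6))
          gap_h <- max(round(gap_h * 60 / dt), 2) * dt / 60
          add_colony_fixes(t_cursor, t_cursor + gap_h)
          t_cursor <- t_cursor + gap_h

          is_land <- stats::runif(1) < cfg$land_excursion_prob
          p_out <- stats::plogis(alpha_out + b_out)
          if (cfg$p_outside[ykey] == 0) p_out <- 0
          if (cfg$p_outside[ykey] == 1) p_out <- 1
          is_out <- !is_land && stats::runif(1) < p_out

          if (is_land) {
            # excursion onto the north shore: short range, long dwell
            bearing <- stats::runif(1, -20, 20) %% 360
            range_km <- stats::runif(1, 5, 7.5)
            dur_h <- stats::runif(1, 1.5, 3)
            type <- "land"
          } else if (is_out) {
            bearing <- stats::runif(1, west_bearings[1] + 4, west_bearings[2] - 4) %% 360
            d_exit <- .ray_to_ring(colony, bearing, area)
            lo <- log(d_exit + 1.5)
            r <- stats::rnorm(1, log(cfg$outside_median_km[ykey]) + b_range,
                              cfg$outside_log_sd[ykey])
            range_km <- min(exp(max(r, lo)), 380)
            dwell <- max(exp(stats::rnorm(1, log(2), 0.5)), 0.4)
            dur_h <- 2 * range_km / speed + dwell
            type <- "outside"
          } else {
            bearing <- stats::runif(1, 0, 360)
            cap <- 0.85 * .ray_to_ring(colony, bearing, area)
            tries <- 0
            while (cap < 2.5 && tries < 10) {
              bearing <- stats::runif(1, 0, 360)
              cap <- 0.85 * .ray_to_ring(colony, bearing, area)
              tries <- tries + 1
            }
            r <- exp(stats::rnorm(1, log(cfg$inside_median_km[ykey]) + b_range,
                                  cfg$inside_log_sd))
            range_km <- min(max(r, 1), cap)
            dwell <- max(exp(stats::rnorm(1, log(0.8), 0.5)), 0.3)
            dur_h <- max(2 * range_km / speed + dwell, 1.2)
            type <- "inside"
          }
          tr <- .render_track(colony, bearing, range_km, dur_h, speed, dt)
          bird_fix_t <- c(bird_fix_t, t_cursor + tr$t_h)
          bird_fix_lon <- c(bird_fix_lon, tr$lon)
          bird_fix_lat <- c(bird_fix_lat, tr$lat)
          gt_trips[[length(gt_trips) + 1L]] <- data.frame(
            bird_id = bird_id, colony_id = colony_id, year = yr, trip_index = k,
            type = type, max_range_km = range_km,
            start_h = t_cursor + dt / 60,
            end_h = t_cursor + tr$T_h - dt / 60,
            stringsAsFactors = FALSE)
          t_cursor <- t_cursor + tr$T_h
        }
        add_colony_fixes(t_cursor, t_cursor + 2 * dt / 60)
        t_cursor <- t_cursor + 2 * dt / 60

        truncated <- stats::runif(1) < cfg$battery_failure_prob
        if (truncated && length(bird_fix_t) > 10) {
          # battery dies during (or just after) the last trip, so the cut
          # point decides whether the 75%-return retention rule fires
          last_gt <- gt_trips[[length(gt_trips)]]
          cut_h <- stats::runif(1, (last_gt$start_h + last_gt$end_h) / 2,
                                last_gt$end_h + 2 * dt / 60)
          keep <- bird_fix_t <= cut_h
          bird_fix_t <- bird_fix_t[keep]
          bird_fix_lon <- bird_fix_lon[keep]
          bird_fix_lat <- bird_fix_lat[keep]
          t_cursor <- cut_h
        }
        recapture <- capture + round(3600 * (t_cursor + dt / 60))

        dup <- duplicated(round(bird_fix_t * 3600))
        fixes[[length(fixes) + 1L]] <- data.frame(
          bird_id = bird_id,
          timestamp = capture + round(3600 * bird_fix_t[!dup]),
          lon = bird_fix_lon[!dup], lat = bird_fix_lat[!dup],
          stringsAsFactors = FALSE)
        deployments[[length(deployments) + 1L]] <- data.frame(
          dep_id = bird_no, bird_id = bird_id, colony_id = colony_id,
          year = yr, capture_time = capture, recapture_time = recapture,
          stringsAsFactors = FALSE)

        # morphometrics driven by the realized trips
        sex <- sample(c("female", "male"), 1)
        hb <- stats::rnorm(1, if (sex == "female") cfg$headbill_female_mean
                           else cfg$headbill_male_mean, cfg$headbill_sd)
        mass_c <- 5 * round((cfg$condition_intercept + cfg$condition_slope * hb +
                               stats::rnorm(1, 0, cfg$condition_resid_sd)) / 5)
        tr_types <- vapply(gt_trips[(length(gt_trips) - n_trips + 1):length(gt_trips)],
                           function(g) g$type, character(1))
        n_out <- sum(tr_types == "outside")
        n_eff <- sum(tr_types != "land")
        prop_out <- if (n_eff > 0) n_out / n_eff else 0
        bmc <- cfg$bmc_prop_slope * prop_out + cfg$bmc_year_levels[ykey] +
          cfg$bmc_colony_effect * (colony_id == "OSS") +
          stats::rnorm(1, 0, cfg$bmc_bird_sd) + stats::rnorm(1, 0, cfg$bmc_resid_sd)
        mass_r <- 5 * round(mass_c * (1 + bmc) / 5)
        morpho[[length(morpho) + 1L]] <- data.frame(
          bird_id = bird_id, colony_id = colony_id, year = yr,
          sex_molecular = if (stats::runif(1) < cfg$molecular_sex_prob) sex else NA_character_,
          head_bill_mm = round(hb), mass_capture_g = mass_c,
          mass_recapture_g = mass_r, stringsAsFactors = FALSE)
        gt_birds[[length(gt_birds) + 1L]] <- data.frame(
          bird_id = bird_id, colony_id = colony_id, year = yr, sex = sex,
          b_range = b_range, b_out = b_out, n_trips = n_trips,
          prop_outside_true = prop_out, bmc_true = bmc,
          truncated = truncated, stringsAsFactors = FALSE)
      }
    }
  }

  net_samples <- .simulate_netsamples(cfg)

  structure(list(
    fixes = do.call(rbind, fixes),
    deployments = do.call(rbind, deployments),
    morpho = do.call(rbind, morpho),
    net_samples = net_samples$samples,
    dry_mass = net_samples$dry_mass,
    area = area,
    ground_truth = list(trips = do.call(rbind, gt_trips),
                        birds = do.call(rbind, gt_birds),
                        config = cfg)),
    class = "cpf_study")
}

# five stations x five depth strata x four prey taxa; abundances gamma
# around station- and year-scaled means
.simulate_netsamples <- function(cfg) {
  dry_mass <- data.frame(
    species_id = c("cal_fin", "cal_gla", "thy_iner", "lim_hel"),
    dry_mass_mg = c(0.20, 0.45, 6.0, 0.9),
    stringsAsFactors = FALSE)
  base_ab <- c(cal_fin = 60, cal_gla = 35, thy_iner = 0.8, lim_hel = 6)
  strata <- data.frame(top = c(0, 20, 50, 100, 200),
                       bottom = c(20, 50, 100, 200, 300))
  rows <- list()
  for (yr in cfg$years) {
    ysc <- cfg$zoo_year_scale[as.character(yr)]
    for (st in 1:5) {
      st_sc <- exp(stats::rnorm(1, 0, 0.3))
      for (si in seq_len(nrow(strata))) {
        depth_sc <- exp(-0.006 * strata$top[si])
        for (sp in names(base_ab)) {
          mu <- base_ab[[sp]] * ysc * st_sc * depth_sc
          ab <- stats::rgamma(1, shape = 4, rate = 4 / mu)
          rows[[length(rows) + 1L]] <- data.frame(
            year = yr, station_id = paste0("st", st),
            top_depth_m = strata$top[si], bottom_depth_m = strata$bottom[si],
            species_id = sp, abundance_ind_m3 = ab, stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(samples = do.call(rbind, rows), dry_mass = dry_mass)
}

#' @export
print.cpf_study <- function(x, ...) {
  cat(sprintf("Synthetic study: %d fixes, %d deployments, %d birds, %d net-sample rows\n",
              nrow(x$fixes), nrow(x$deployments), nrow(x$morpho),
              nrow(x$net_samples)))
  invisible(x)
}

#' Write a synthetic study to CSV/GeoJSON files
#'
#' Emits \code{fixes.csv}, \code{deployments.csv}, \code{morpho.csv},
#' \code{net_samples.csv}, \code{dry_mass.csv}, \code{area.geojson} and
#' \code{ground_truth.json} under \code{outdir}.
#'
#' @param study A \code{cpf_study}.
#' @param outdir Output directory (created if needed).
#' @return \code{outdir}, invisibly.
#' @export
write_study <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  fx <- study$fixes
  fx$timestamp <- fmt(fx$timestamp)
  utils::write.csv(fx, file.path(outdir, "fixes.csv"), row.names = FALSE)
  dp <- study$deployments
  dp$capture_time <- fmt(dp$capture_time)
  dp$recapture_time <- fmt(dp$recapture_time)
  utils::write.csv(dp, file.path(outdir, "deployments.csv"), row.names = FALSE)
  utils::write.csv(study$morpho, file.path(outdir, "morpho.csv"), row.names = FALSE)
  utils::write.csv(study$net_samples, file.path(outdir, "net_samples.csv"),
                   row.names = FALSE)
  utils::write.csv(study$dry_mass, file.path(outdir, "dry_mass.csv"),
                   row.names = FALSE)
  write_study_area(study$area, file.path(outdir, "area.geojson"))
  gt <- study$ground_truth
  gt$config <- unclass(gt$config)
  gt$trips$start_h <- round(gt$trips$start_h, 6)
  gt$trips$end_h <- round(gt$trips$end_h, 6)
  jsonlite::write_json(gt, file.path(outdir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, POSIXt = "ISO8601")
  invisible(outdir)
}
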