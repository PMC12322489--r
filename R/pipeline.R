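#' Pipeline run configuration
#'
#' Bundles the analysis constants and per-stage seeds for a full run:
#' segmentation thresholds (0.2 km colony radius, 50 min minimum
#' duration, 10-min subsampling), the land (50\%) and incomplete-trip
#' (75\% return) filters, the bimodality settings (0-200 km mode window,
#' 999 resampling iterations, alpha 0.05) and the MCMC settings.
#'
#' @param simulate Simulate a synthetic study (TRUE) or use supplied
#'   input tables.
#' @param sim A \code{cpf_sim_config} when simulating.
#' @param seeds Named list of integer seeds per stage.
#' @param interval_min,min_dist_km,min_duration_min Segmentation.
#' @param max_land_fraction,return_fraction Trip filters.
#' @param limits,iterations,alpha,n_null Bimodality settings.
#' @param n_boot Bootstrap iterations for proportions and biomass.
#' @param chains,mcmc_iterations,warmup MCMC settings.
#' @param stages Character vector of stages to run (subset of
#'   \code{c("segment", "bimodality", "condition", "models",
#'   "zooplankton")}).
#' @return List of class \code{cpf_run_config}.
#' @export
run_config <- function(simulate = TRUE, sim = sim_config(),
                       seeds = list(simulate = 1, bimodality = 2,
                                    condition = 3, models = 4, zooplankton = 5),
                       interval_min = 10, min_dist_km = 0.2, min_duration_min = 50,
                       max_land_fraction = 0.5, return_fraction = 0.75,
                       limits = c(0, 200), iterations = 999, alpha = 0.05,
                       n_null = 2000, n_boot = 999,
                       chains = 5, mcmc_iterations = 6000, warmup = 3000,
                       stages = c("segment", "bimodality", "condition",
                                  "models", "zooplankton")) {
  cfg <- as.list(environment())
  class(cfg) <- "cpf_run_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> segment -> filter -> bimodality ->
#' condition -> models -> zooplankton, logging every filtering decision
#' with counts, and returns a consolidated report mirroring the study's
#' result tables: per-year trip/bird counts, dip tests, mode estimates,
#' resampling checks, weighted outside-trip proportions and biomass
#' indices, plus model summaries and contrasts.
#'
#' @param config A \code{cpf_run_config}.
#' @param inputs When \code{config$simulate} is FALSE: list with
#'   \code{fixes}, \code{deployments}, \code{morpho}, \code{net_samples},
#'   \code{dry_mass}, \code{area}.
#' @param quiet Suppress progress messages.
#' @return List of class \code{cpf_report}.
#' @export
run_pipeline <- function(config = run_config(), inputs = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  report <- list(config_constants = list(
    min_dist_km = config$min_dist_km, min_duration_min = config$min_duration_min,
    interval_min = config$interval_min, max_land_fraction = config$max_land_fraction,
    return_fraction = config$return_fraction, limits = config$limits,
    iterations = config$iterations, alpha = config$alpha))

  if (config$simulate) {
    say("stage simulate: generating synthetic study (seed %d)", config$seeds$simulate)
    study <- simulate_study(config$sim, seed = config$seeds$simulate)
    inputs <- study
    report$simulated <- TRUE
  } else {
    if (is.null(inputs)) stop("run_pipeline: inputs required when simulate = FALSE")
    report$simulated <- FALSE
  }

  trips <- NULL
  if ("segment" %in% config$stages) {
    say("stage segment: delineating trips")
    raw <- segment_trips(inputs$fixes, inputs$deployments, inputs$area,
                         interval_min = config$interval_min,
                         min_dist_km = config$min_dist_km,
                         min_duration_min = config$min_duration_min)
    n0 <- nrow(raw)
    after_land <- exclude_land_trips(raw, config$max_land_fraction)
    n1 <- nrow(after_land)
    trips <- filter_incomplete(after_land, inputs$area, config$return_fraction)
    n2 <- nrow(trips)
    say("  delineated %d trips; dropped %d by land rule, %d by 75%%-return rule; %d retained",
        n0, n0 - n1, n1 - n2, n2)
    report$segmentation <- list(delineated = n0, dropped_land = n0 - n1,
                                dropped_incomplete = n1 - n2, retained = n2)
    yrs <- sort(unique(trips$year))
    report$per_year <- lapply(stats::setNames(yrs, yrs), function(yr) {
      tr <- trips[trips$year == yr, ]
      list(n_trips = nrow(tr), n_birds = length(unique(tr$bird_id)))
    })
  }

  if ("bimodality" %in% config$stages && !is.null(trips)) {
    say("stage bimodality: per-year dip tests and modes")
    imr <- individual_max_range(trips)
    for (yr in sort(unique(imr$year))) {
      v <- imr$max_range_km[imr$year == yr]
      ykey <- as.character(yr)
      if (length(v) >= 3 && stats::sd(v) > 0) {
        modes <- mode_locations(v, limits = config$limits, alpha = config$alpha,
                                n_null = config$n_null,
                                seed = config$seeds$bimodality)
        tr <- trips[trips$year == yr, ]
        tr <- tr[tr$dep_id %in% unique(trips$dep_id), ]
        rs <- resample_bimodality(tr[, c("bird_id", "max_range_km")],
                                  iterations = config$iterations,
                                  seed = config$seeds$bimodality,
                                  alpha = config$alpha, n_null = config$n_null)
        report$per_year[[ykey]]$dip <- unclass(modes$dip)
        report$per_year[[ykey]]$modes <- list(k = modes$k, modes = modes$modes,
                                              h_crit = modes$h_crit)
        report$per_year[[ykey]]$resampling <- list(
          prop_significant = rs$prop_significant, iterations = rs$iterations)
        say("  %s: D = %.3f (p = %.3g), %d mode(s) at %s km", ykey,
            modes$dip$D, modes$dip$p_value, modes$k,
            paste(sprintf("%.1f", modes$modes), collapse = "/"))
      }
    }
  }

  cond <- NULL
  if ("condition" %in% config$stages && !is.null(trips)) {
    say("stage condition: body condition and weighted proportions")
    cond <- condition_table(inputs$morpho, trips)
    report$condition_regression <- list(
      slope = attr(cond, "slope"), slope_ci = attr(cond, "slope_ci"),
      r_squared = attr(cond, "r_squared"), df = attr(cond, "df"))
    for (yr in sort(unique(cond$year))) {
      cc <- cond[cond$year == yr & !is.na(cond$n_trips), ]
      if (nrow(cc)) {
        wp <- weighted_outside_proportion(cc$prop_outside, cc$n_trips,
                                          n_boot = config$n_boot,
                                          seed = config$seeds$condition)
        report$per_year[[as.character(yr)]]$outside_proportion <- unclass(wp)
        say("  %d: weighted outside proportion %.1f%% [%.1f, %.1f]",
            yr, 100 * wp$estimate, 100 * wp$ci_low, 100 * wp$ci_high)
      }
    }
  }

  if ("models" %in% config$stages && !is.null(trips) && !is.null(cond)) {
    report$models <- list()
    for (lbl in c("inside", "outside")) {
      sub <- trips[trips$label == lbl, ]
      if (nrow(sub) >= 10 && length(unique(sub$year)) > 1) {
        say("stage models: M1 on %s-fjord trips (n=%d)", lbl, nrow(sub))
        fit <- fit_model("M1_logrange", sub, chains = config$chains,
                         iterations = config$mcmc_iterations,
                         warmup = config$warmup, seed = config$seeds$models)
        s <- fit_summary(fit)
        report$models[[paste0("M1_", lbl)]] <- list(
          summary = s$table, convergence_ok = s$convergence_ok)
      }
    }
    say("stage models: M2 outside probability (n=%d)", nrow(trips))
    fit2 <- fit_model("M2_outside", trips, chains = config$chains,
                      iterations = config$mcmc_iterations,
                      warmup = config$warmup, seed = config$seeds$models)
    s2 <- fit_summary(fit2)
    report$models$M2 <- list(summary = s2$table, convergence_ok = s2$convergence_ok)
    cc <- cond[!is.na(cond$n_trips), ]
    say("stage models: M3 first-trip decision (n=%d birds)", nrow(cc))
    fit3 <- fit_model("M3_firsttrip", cc, chains = config$chains,
                      iterations = config$mcmc_iterations,
                      warmup = config$warmup, seed = config$seeds$models)
    s3 <- fit_summary(fit3)
    report$models$M3 <- list(summary = s3$table, convergence_ok = s3$convergence_ok)
    cc4 <- cc[!is.na(cc$bmc), ]
    say("stage models: M4 mass change (n=%d birds)", nrow(cc4))
    fit4 <- fit_model("M4_bmc", cc4, chains = config$chains,
                      iterations = config$mcmc_iterations,
                      warmup = config$warmup, seed = config$seeds$models)
    s4 <- fit_summary(fit4)
    report$models$M4 <- list(summary = s4$table, convergence_ok = s4$convergence_ok)
  }

  if ("zooplankton" %in% config$stages && !is.null(inputs$net_samples)) {
    say("stage zooplankton: yearly biomass indices")
    bm <- biomass_by_year(inputs$net_samples, inputs$dry_mass,
                          n_boot = config$n_boot, seed = config$seeds$zooplankton)
    for (ykey in names(bm)) {
      report$per_year[[ykey]]$biomass <- unclass(bm[[ykey]])
      say("  %s: biomass index %.2f mg m^-3", ykey, bm[[ykey]]$index)
    }
  }

  structure(report, class = "cpf_report")
}

#' Write a report as JSON
#'
#' @param report A \code{cpf_report}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, na = "null")
  invisible(path)
}

#' Validate the structure of a report
#'
#' Lightweight structural check of a (possibly re-read) report: required
#' top-level fields, per-year blocks and model summaries.
#'
#' @param report A \code{cpf_report} or a list parsed from report JSON.
#' @return TRUE, or a character vector of problems.
#' @export
validate_report <- function(report) {
  problems <- character(0)
  need <- function(cond, msg) if (!cond) problems <<- c(problems, msg)
  need(!is.null(report$config_constants), "missing config_constants")
  need(!is.null(report$per_year), "missing per_year")
  for (ykey in names(report$per_year)) {
    y <- report$per_year[[ykey]]
    need(!is.null(y$n_trips), paste0(ykey, ": missing n_trips"))
    need(!is.null(y$n_birds), paste0(ykey, ": missing n_birds"))
  }
  if (length(problems)) problems else TRUE
}

#' @export
print.cpf_report <- function(x, ...) {
  cat("Pipeline report\n")
  for (ykey in names(x$per_year)) {
    y <- x$per_year[[ykey]]
    cat(sprintf("  %s: %d trips, %d birds", ykey, y$n_trips, y$n_birds))
    if (!is.null(y$dip)) cat(sprintf("; D = %.3f (p = %.3g)", y$dip$D, y$dip$p_value))
    if (!is.null(y$outside_proportion)) {
      cat(sprintf("; outside %.1f%%", 100 * y$outside_proportion$estimate))
    }
    cat("\n")
  }
  invisible(x)
}
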