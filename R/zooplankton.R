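#' Station-level zooplankton dry biomass
#'
#' For one station and year: each species' abundance (ind m^-3) is
#' averaged over the station's depth strata (unweighted by stratum
#' thickness, matching the monitoring programme's depth-strata averaging),
#' multiplied by its individual dry mass, and summed over species.
#'
#' @param samples Data frame for one station-year: \code{top_depth_m},
#'   \code{bottom_depth_m}, \code{species_id}, \code{abundance_ind_m3}.
#' @param dry_mass Data frame: \code{species_id}, \code{dry_mass_mg}.
#' @param weight_by_thickness Average strata weighted by thickness instead
#'   (default FALSE).
#' @return Station biomass, mg dry mass m^-3.
#' @export
station_biomass <- function(samples, dry_mass, weight_by_thickness = FALSE) {
  if (nrow(samples) == 0) stop("station_biomass: no strata")
  missing <- setdiff(unique(samples$species_id), dry_mass$species_id)
  if (length(missing)) {
    stop("station_biomass: no dry mass for species: ",
         paste(missing, collapse = ", "))
  }
  total <- 0
  for (sp in unique(samples$species_id)) {
    rows <- samples[samples$species_id == sp, ]
    ab <- if (weight_by_thickness) {
      w <- rows$bottom_depth_m - rows$top_depth_m
      sum(rows$abundance_ind_m3 * w) / sum(w)
    } else {
      mean(rows$abundance_ind_m3)
    }
    total <- total + ab * dry_mass$dry_mass_mg[match(sp, dry_mass$species_id)]
  }
  total
}

#' Yearly seasonal zooplankton biomass index
#'
#' Fjord-level index for one year: the mean of the station biomass
#' values, with a 2.5/97.5 percentile CI from bootstrapping stations with
#' replacement.
#'
#' @param station_values Numeric vector of station biomass estimates
#'   (mg m^-3), one per station.
#' @param n_boot Bootstrap iterations (default 999).
#' @param seed Integer seed.
#' @return Object of class \code{cpf_biomass}: list with \code{index},
#'   \code{ci_low}, \code{ci_high}, \code{n_boot}, \code{seed},
#'   \code{n_stations}.
#' @export
yearly_index <- function(station_values, n_boot = 999, seed = 1) {
  if (length(station_values) == 0) stop("yearly_index: no stations")
  idx <- mean(station_values)
  bs <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      mean(sample(station_values, replace = TRUE))
    }, numeric(1))
  })
  qs <- stats::quantile(bs, c(0.025, 0.975), names = FALSE)
  structure(list(index = idx, ci_low = qs[1], ci_high = qs[2],
                 n_boot = n_boot, seed = seed,
                 n_stations = length(station_values)),
            class = "cpf_biomass")
}

#' @export
print.cpf_biomass <- function(x, ...) {
  cat(sprintf("Zooplankton biomass index: %.2f mg m^-3 [%.2f, %.2f] over %d stations\n",
              x$index, x$ci_low, x$ci_high, x$n_stations))
  invisible(x)
}

#' Biomass indices for all station-years in a net-sample table
#'
#' @param net_samples Data frame: \code{year}, \code{station_id},
#'   \code{top_depth_m}, \code{bottom_depth_m}, \code{species_id},
#'   \code{abundance_ind_m3}.
#' @param dry_mass Data frame: \code{species_id}, \code{dry_mass_mg}.
#' @param n_boot,seed Passed to [yearly_index()].
#' @param weight_by_thickness Passed to [station_biomass()].
#' @return Named list (by year) of \code{cpf_biomass} objects.
#' @export
biomass_by_year <- function(net_samples, dry_mass, n_boot = 999, seed = 1,
                            weight_by_thickness = FALSE) {
  out <- list()
  for (yr in sort(unique(net_samples$year))) {
    ydat <- net_samples[net_samples$year == yr, ]
    sv <- vapply(sort(unique(ydat$station_id)), function(st) {
      station_biomass(ydat[ydat$station_id == st, ], dry_mass,
                      weight_by_thickness)
    }, numeric(1))
    out[[as.character(yr)]] <- yearly_index(sv, n_boot, seed + as.integer(yr) %% 1000L)
  }
  out
}
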