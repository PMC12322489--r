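# shared fixtures: a tiny square study area, fix-table builders, and a
# cached clean synthetic study (no battery failure, no land excursions)

unit_square <- cbind(lon = c(0, 1, 1, 0, 0), lat = c(0, 0, 1, 1, 0))

# small area: 1x1 degree fjord at the equator with a land strip on top
tiny_area <- function() {
  study_area(
    fjord = unit_square,
    land = list(cbind(lon = c(0, 1, 1, 0, 0), lat = c(1, 1, 2, 2, 1))),
    colonies = list(C1 = c(0.5, 0.5))
  )
}

# fixes at given minute offsets / positions for one bird
make_fixes <- function(minutes, lon, lat, bird_id = "b1",
                       t0 = as.POSIXct("2018-07-01 00:00:00", tz = "UTC")) {
  data.frame(bird_id = bird_id, timestamp = t0 + minutes * 60,
             lon = lon, lat = lat, stringsAsFactors = FALSE)
}

# build a cpf_trips table by hand from a list of per-trip fix frames
make_trips_table <- function(fix_list, colony, area,
                             complete = rep(TRUE, length(fix_list)),
                             colony_id = "C1", year = 2018) {
  rows <- lapply(seq_along(fix_list), function(i) {
    f <- fix_list[[i]]
    m <- trip_metrics(list(fixes = f), colony)
    data.frame(dep_id = i, bird_id = unique(f$bird_id)[1], colony_id = colony_id,
               year = year, trip_index = i, start = f$timestamp[1],
               end = f$timestamp[nrow(f)], n_fixes = nrow(f),
               max_range_km = unname(m["max_range_km"]),
               duration_h = unname(m["duration_h"]),
               land_fraction = land_fraction(f, area),
               complete = complete[i],
               label = classify_trip(f, area), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "trip_fixes") <- fix_list
  class(out) <- c("cpf_trips", class(out))
  out
}

.fixture_cache <- new.env(parent = emptyenv())

# clean study: every generated trip survives segmentation unchanged
clean_study <- function(seed = 5) {
  key <- paste0("clean", seed)
  if (is.null(.fixture_cache[[key]])) {
    cfg <- sim_config(battery_failure_prob = 0, land_excursion_prob = 0)
    .fixture_cache[[key]] <- simulate_study(cfg, seed = seed)
  }
  .fixture_cache[[key]]
}

default_study <- function(seed = 11) {
  key <- paste0("default", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_study(sim_config(), seed = seed)
  }
  .fixture_cache[[key]]
}

segmented_trips <- function(study) {
  key <- paste0("trips", substr(digest_ish(study), 1, 12))
  raw <- segment_trips(study$fixes, study$deployments, study$area)
  filter_incomplete(exclude_land_trips(raw), study$area)
}

# cheap structural hash to key the cache without external deps
digest_ish <- function(study) {
  paste0(nrow(study$fixes), "_", round(sum(study$fixes$lon) * 1000))
}
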