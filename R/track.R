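#' Subsample a fix series to a standard interval
#'
#' Greedy forward pass: keep the first fix, then every next fix whose time
#' gap from the last kept fix is at least \code{interval_min} minutes. No
#' interpolation is performed, so all output positions are observed
#' positions and the output is a subset of the input.
#'
#' @param fixes Data frame with a \code{timestamp} column (POSIXct),
#'   strictly increasing.
#' @param interval_min Target interval in minutes (default 10).
#' @return The subsampled data frame.
#' @export
subsample_fixes <- function(fixes, interval_min = 10) {
  n <- nrow(fixes)
  if (n == 0) return(fixes)
  tt <- as.numeric(fixes$timestamp)
  if (n > 1 && any(diff(tt) <= 0)) {
    stop("subsample_fixes: timestamps must be strictly increasing")
  }
  keep <- logical(n)
  keep[1] <- TRUE
  last <- tt[1]
  gap <- interval_min * 60
  for (i in seq_len(n)[-1]) {
    if (tt[i] - last >= gap) {
      keep[i] <- TRUE
      last <- tt[i]
    }
  }
  fixes[keep, , drop = FALSE]
}

#' Delineate foraging trips from a fix series
#'
#' A foraging trip is a maximal run of consecutive fixes farther than
#' \code{min_dist_km} from the colony centre, lasting at least
#' \code{min_duration_min} minutes (elapsed time from the first to the
#' last above-threshold fix). Colony-attendance fixes are not part of
#' trips. A trip is complete when the fix immediately after the run exists
#' and is back within \code{min_dist_km} of the colony; a run cut off by
#' the end of the series (battery failure, logger retrieval) is
#' incomplete.
#'
#' @param fixes Data frame with \code{timestamp}, \code{lon}, \code{lat}
#'   (one deployment, already subsampled).
#' @param colony Length-2 numeric \code{c(lon, lat)}.
#' @param min_dist_km Colony-attendance radius in km (default 0.2, i.e.
#'   200 m).
#' @param min_duration_min Minimum trip duration in minutes (default 50).
#' @return List of trips; each trip is a list with elements \code{fixes}
#'   (data frame) and \code{complete} (logical).
#' @export
delineate_trips <- function(fixes, colony, min_dist_km = 0.2,
                            min_duration_min = 50) {
  if (is.null(fixes) || nrow(fixes) == 0) return(list())
  d <- haversine_km(fixes$lon, fixes$lat, colony[1], colony[2])
  away <- d > min_dist_km
  if (!any(away)) return(list())
  r <- rle(away)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  trips <- list()
  tt <- as.numeric(fixes$timestamp)
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    s <- starts[i]
    e <- ends[i]
    if ((tt[e] - tt[s]) / 60 < min_duration_min) next
    complete <- e < nrow(fixes) # next fix exists and is <= min_dist_km by runs
    trips[[length(trips) + 1L]] <- list(fixes = fixes[s:e, , drop = FALSE],
                                        complete = complete)
  }
  trips
}

#' Maximum range and duration of a trip
#'
#' @param trip A trip as returned by [delineate_trips()] (or any list
#'   with a \code{fixes} data frame).
#' @param colony Length-2 numeric \code{c(lon, lat)}.
#' @return Named numeric: \code{max_range_km} (greatest haversine distance
#'   from the colony over the trip's fixes) and \code{duration_h} (elapsed
#'   first-to-last fix, hours).
#' @export
trip_metrics <- function(trip, colony) {
  f <- trip$fixes
  if (nrow(f) == 0) stop("trip_metrics: trip has no fixes")
  d <- haversine_km(f$lon, f$lat, colony[1], colony[2])
  tt <- as.numeric(f$timestamp)
  c(max_range_km = max(d), duration_h = (tt[length(tt)] - tt[1]) / 3600)
}

#' Segment deployments into a trip table
#'
#' Full segmentation for a study: subsamples each deployment's fixes,
#' delineates trips, computes metrics, the land-overlap fraction and the
#' inside/outside-fjord label. Returns one row per delineated trip
#' (before any filtering), with the per-trip fixes attached as an
#' attribute.
#'
#' @param fixes Data frame of raw fixes: \code{bird_id}, \code{timestamp}
#'   (POSIXct, UTC), \code{lon}, \code{lat}.
#' @param deployments Data frame: \code{dep_id}, \code{bird_id},
#'   \code{colony_id}, \code{year}, \code{capture_time},
#'   \code{recapture_time}. If \code{dep_id} is missing, rows are numbered.
#' @param area A \code{cpf_study_area}.
#' @param interval_min,min_dist_km,min_duration_min Segmentation
#'   constants; defaults 10 min, 0.2 km, 50 min.
#' @return Data frame of class \code{cpf_trips} with columns
#'   \code{dep_id}, \code{bird_id}, \code{colony_id}, \code{year},
#'   \code{trip_index}, \code{start}, \code{end}, \code{n_fixes},
#'   \code{max_range_km}, \code{duration_h}, \code{land_fraction},
#'   \code{complete}, \code{label}; attribute \code{trip_fixes} holds the
#'   per-trip fix data frames.
#' @export
segment_trips <- function(fixes, deployments, area, interval_min = 10,
                          min_dist_km = 0.2, min_duration_min = 50) {
  if (is.null(deployments$dep_id)) deployments$dep_id <- seq_len(nrow(deployments))
  rows <- list()
  all_fixes <- list()
  for (i in seq_len(nrow(deployments))) {
    dep <- deployments[i, ]
    colony <- area$colonies[[as.character(dep$colony_id)]]
    if (is.null(colony)) stop("segment_trips: unknown colony '", dep$colony_id, "'")
    f <- fixes[fixes$bird_id == dep$bird_id &
                 fixes$timestamp >= dep$capture_time &
                 fixes$timestamp <= dep$recapture_time, , drop = FALSE]
    f <- f[order(f$timestamp), , drop = FALSE]
    if (nrow(f) == 0) next
    f <- subsample_fixes(f, interval_min)
    trips <- delineate_trips(f, colony, min_dist_km, min_duration_min)
    for (k in seq_along(trips)) {
      tr <- trips[[k]]
      m <- trip_metrics(tr, colony)
      rows[[length(rows) + 1L]] <- data.frame(
        dep_id = dep$dep_id,
        bird_id = dep$bird_id,
        colony_id = dep$colony_id,
        year = dep$year,
        trip_index = k,
        start = tr$fixes$timestamp[1],
        end = tr$fixes$timestamp[nrow(tr$fixes)],
        n_fixes = nrow(tr$fixes),
        max_range_km = unname(m["max_range_km"]),
        duration_h = unname(m["duration_h"]),
        land_fraction = land_fraction(tr$fixes, area),
        complete = tr$complete,
        label = classify_trip(tr$fixes, area),
        stringsAsFactors = FALSE)
      all_fixes[[length(all_fixes) + 1L]] <- tr$fixes
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(dep_id = integer(), bird_id = character(), colony_id = character(),
               year = integer(), trip_index = integer(), start = as.POSIXct(character()),
               end = as.POSIXct(character()), n_fixes = integer(),
               max_range_km = numeric(), duration_h = numeric(),
               land_fraction = numeric(), complete = logical(),
               label = character(), stringsAsFactors = FALSE)
  attr(out, "trip_fixes") <- all_fixes
  class(out) <- c("cpf_trips", class(out))
  out
}

# subset a trip table, keeping the trip_fixes attribute aligned
.subset_trips <- function(trips, keep) {
  fx <- attr(trips, "trip_fixes")
  out <- trips[keep, , drop = FALSE]
  if (!is.null(fx)) attr(out, "trip_fixes") <- fx[keep]
  class(out) <- class(trips)
  out
}

#' Drop trips dominated by land positions
#'
#' Trips with strictly more than half of their fixes overlapping land are
#' removed: birds collecting nest material or bathing in freshwater are
#' not foraging. Exactly 50\% on land is retained ("more than" is
#' strict).
#'
#' @param trips A \code{cpf_trips} table (with \code{land_fraction}).
#' @param max_land_fraction Threshold (default 0.5).
#' @return Filtered trip table.
#' @export
exclude_land_trips <- function(trips, max_land_fraction = 0.5) {
  .subset_trips(trips, trips$land_fraction <= max_land_fraction)
}

#' Retain incomplete trips only when mostly completed
#'
#' Complete trips are always retained. A trip cut short (battery failure)
#' is retained only when the bird had returned towards the colony, having
#' covered at least 75\% of the maximum distance reached: the final fix
#' must lie within \code{1 - return_fraction} (default 25\%) of the
#' maximum range from the colony. An alternative reading based on
#' cumulative path length is available via \code{method = "path_length"}
#' (retain when the travelled path is at least \code{return_fraction}
#' of twice the maximum range).
#'
#' @param trips A \code{cpf_trips} table.
#' @param area The study area (for colony coordinates).
#' @param return_fraction Fraction of the maximum range that must have
#'   been covered on the return (default 0.75).
#' @param method \code{"final_distance"} (default) or
#'   \code{"path_length"}.
#' @return Filtered trip table.
#' @export
filter_incomplete <- function(trips, area, return_fraction = 0.75,
                              method = c("final_distance", "path_length")) {
  method <- match.arg(method)
  fx <- attr(trips, "trip_fixes")
  keep <- logical(nrow(trips))
  for (i in seq_len(nrow(trips))) {
    if (isTRUE(trips$complete[i])) {
      keep[i] <- TRUE
      next
    }
    f <- fx[[i]]
    colony <- area$colonies[[as.character(trips$colony_id[i])]]
    if (method == "final_distance") {
      last_d <- haversine_km(f$lon[nrow(f)], f$lat[nrow(f)], colony[1], colony[2])
      thr <- (1 - return_fraction) * trips$max_range_km[i]
      keep[i] <- last_d <= thr * (1 + 1e-9) # boundary counts as returned
    } else {
      steps <- haversine_km(f$lon[-nrow(f)], f$lat[-nrow(f)],
                            f$lon[-1], f$lat[-1])
      keep[i] <- sum(steps) >= return_fraction * 2 * trips$max_range_km[i]
    }
  }
  .subset_trips(trips, keep)
}

#' Per-individual maximum foraging range
#'
#' One value per individual and year: the maximum range over all retained
#' trips of that individual's first deployment of the year (repeat
#' deployments are excluded to avoid pseudo-replication). Individuals
#' with no retained trips are dropped with a warning.
#'
#' @param trips A (filtered) \code{cpf_trips} table.
#' @param first_deployment_only Use only the first deployment per
#'   bird-year (default TRUE).
#' @return Data frame: \code{bird_id}, \code{year}, \code{max_range_km},
#'   \code{n_trips}.
#' @export
individual_max_range <- function(trips, first_deployment_only = TRUE) {
  if (nrow(trips) == 0) {
    return(data.frame(bird_id = character(), year = integer(),
                      max_range_km = numeric(), n_trips = integer()))
  }
  df <- as.data.frame(trips)
  if (first_deployment_only) {
    # first deployment per bird-year = smallest dep start
    dep_start <- stats::aggregate(start ~ dep_id + bird_id + year, df, min)
    dep_start <- dep_start[order(dep_start$start), ]
    first_dep <- dep_start[!duplicated(dep_start[c("bird_id", "year")]), "dep_id"]
    df <- df[df$dep_id %in% first_dep, , drop = FALSE]
  }
  agg <- stats::aggregate(max_range_km ~ bird_id + year, df, max)
  cnt <- stats::aggregate(trip_index ~ bird_id + year, df, length)
  names(cnt)[3] <- "n_trips"
  merge(agg, cnt, by = c("bird_id", "year"))
}

#' Write / read a trip table as CSV
#'
#' Round-trips the tabular part of a \code{cpf_trips} object (the
#' per-trip fixes are not serialised).
#'
#' @param trips Trip table.
#' @param path Output path.
#' @return \code{path} (write) / data frame (read), invisibly for write.
#' @export
write_trips_csv <- function(trips, path) {
  df <- as.data.frame(trips)
  df$start <- format(df$start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  df$end <- format(df$end, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trips_csv
#' @export
read_trips_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$start <- as.POSIXct(df$start, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  df$end <- as.POSIXct(df$end, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  df
}
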