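#' Great-circle distance between two points
#'
#' Haversine distance on a sphere of radius 6371.0 km. Planar approximations
#' are avoided deliberately: trips in high-Arctic fjord systems can reach
#' several hundred kilometres from the colony, where the flat-earth error is
#' no longer negligible.
#'
#' @param lon1,lat1 Coordinates of the first point (decimal degrees, WGS84).
#' @param lon2,lat2 Coordinates of the second point. All four arguments are
#'   recycled to a common length, so one end can be a fixed colony location
#'   and the other a vector of fixes.
#' @return Distance(s) in kilometres.
#' @examples
#' haversine_km(0, 0, 1, 0)  # one degree of longitude at the equator
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  if (!all(is.finite(c(lon1, lat1, lon2, lat2)))) {
    stop("haversine_km: coordinates must be finite numbers")
  }
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180)) {
    stop("haversine_km: coordinates outside [-180,180] x [-90,90]")
  }
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  6371.0 * 2 * asin(pmin(1, sqrt(a)))
}

#' Test whether points fall inside a polygon
#'
#' Even-odd rule in the raw longitude/latitude plane (no projection), with
#' points on the boundary counted as inside. Adequate for the synthetic
#' study geometry used here; for real coastlines at high latitude a
#' projected test would be preferable.
#'
#' @param lon,lat Point coordinates (vectors of equal length).
#' @param ring Two-column matrix (lon, lat) of polygon vertices. The ring
#'   may be open or closed; it must contain at least three distinct
#'   vertices.
#' @return Logical vector, \code{TRUE} when the point is inside or on the
#'   boundary.
#' @export
point_in_polygon <- function(lon, lat, ring) {
  ring <- as.matrix(ring)
  if (ncol(ring) != 2) stop("point_in_polygon: ring must have two columns (lon, lat)")
  # drop closing vertex if present, then check degeneracy
  if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ])) {
    ring <- ring[-nrow(ring), , drop = FALSE]
  }
  if (nrow(unique(ring)) < 3) {
    stop("point_in_polygon: degenerate ring (fewer than 3 distinct vertices)")
  }
  code <- sp::point.in.polygon(lon, lat, ring[, 1], ring[, 2])
  code > 0
}

#' Assemble a study area
#'
#' @param fjord Two-column matrix (lon, lat): the fjord boundary ring.
#' @param land List of two-column matrices, one per land polygon (may be
#'   empty).
#' @param colonies Named list of length-2 numeric vectors \code{c(lon, lat)},
#'   one per colony.
#' @return An object of class \code{cpf_study_area}.
#' @export
study_area <- function(fjord, land = list(), colonies = list()) {
  fjord <- as.matrix(fjord)
  stopifnot(is.list(land), is.list(colonies))
  for (nm in names(colonies)) {
    p <- colonies[[nm]]
    if (!point_in_polygon(p[1], p[2], fjord)) {
      stop("study_area: colony '", nm, "' lies outside the fjord ring")
    }
  }
  structure(list(fjord = fjord, land = land, colonies = colonies),
            class = "cpf_study_area")
}

#' @export
print.cpf_study_area <- function(x, ...) {
  cat("Study area:", nrow(x$fjord), "fjord ring vertices,",
      length(x$land), "land polygon(s),",
      length(x$colonies), "colony(ies):",
      paste(names(x$colonies), collapse = ", "), "\n")
  invisible(x)
}

#' Read a study area from GeoJSON
#'
#' Expects one Polygon feature with property \code{label = "fjord"}, any
#' number of Polygon features with \code{label = "land"}, and Point features
#' carrying a \code{colony_id} property.
#'
#' @param path Path to a GeoJSON file.
#' @return A \code{cpf_study_area}.
#' @export
read_study_area <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("read_study_area: not a GeoJSON FeatureCollection")
  fjord <- NULL
  land <- list()
  colonies <- list()
  for (ft in gj$features) {
    geom <- ft$geometry
    props <- ft$properties
    if (identical(geom$type, "Polygon")) {
      ring <- do.call(rbind, lapply(geom$coordinates[[1]], function(p) {
        c(p[[1]], p[[2]])
      }))
      if (identical(props$label, "fjord")) {
        fjord <- ring
      } else if (identical(props$label, "land")) {
        land[[length(land) + 1L]] <- ring
      }
    } else if (identical(geom$type, "Point")) {
      if (!is.null(props$colony_id)) {
        colonies[[props$colony_id]] <- c(geom$coordinates[[1]], geom$coordinates[[2]])
      }
    }
  }
  if (is.null(fjord)) stop("read_study_area: no polygon with label 'fjord' found")
  study_area(fjord, land, colonies)
}

#' Write a study area to GeoJSON
#'
#' Inverse of [read_study_area()].
#'
#' @param area A \code{cpf_study_area}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_study_area <- function(area, path) {
  poly_feature <- function(ring, label) {
    ring <- as.matrix(ring)
    if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
    list(type = "Feature",
         properties = list(label = label),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) as.list(ring[i, ])))))
  }
  feats <- c(list(poly_feature(area$fjord, "fjord")),
             lapply(area$land, poly_feature, label = "land"),
             lapply(names(area$colonies), function(nm) {
               list(type = "Feature",
                    properties = list(colony_id = nm),
                    geometry = list(type = "Point",
                                    coordinates = as.list(area$colonies[[nm]])))
             }))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Classify a trip as inside- or outside-fjord
#'
#' A trip is labelled \code{"outside"} if at least one of its fixes falls
#' strictly outside the fjord boundary ring; fixes exactly on the ring count
#' as inside, because remaining within fjord boundaries is the default
#' (0-coded) state.
#'
#' @param fixes Data frame with columns \code{lon} and \code{lat}.
#' @param area A \code{cpf_study_area}.
#' @return \code{"inside"} or \code{"outside"}.
#' @export
classify_trip <- function(fixes, area) {
  if (is.null(fixes) || nrow(fixes) == 0) stop("classify_trip: trip has no fixes")
  inside <- point_in_polygon(fixes$lon, fixes$lat, area$fjord)
  if (all(inside)) "inside" else "outside"
}

#' Fraction of fixes overlapping land
#'
#' @param fixes Data frame with columns \code{lon} and \code{lat}.
#' @param area A \code{cpf_study_area}.
#' @return Proportion of fixes falling inside any land polygon.
#' @export
land_fraction <- function(fixes, area) {
  if (nrow(fixes) == 0) return(0)
  if (length(area$land) == 0) return(0)
  on_land <- rep(FALSE, nrow(fixes))
  for (poly in area$land) {
    on_land <- on_land | point_in_polygon(fixes$lon, fixes$lat, poly)
  }
  mean(on_land)
}

# great-circle destination point: start (lon,lat) deg, bearing deg
# (clockwise from north), distance km on the 6371-km sphere
destination_point <- function(lon, lat, bearing_deg, dist_km) {
  rad <- pi / 180
  d <- dist_km / 6371.0
  br <- bearing_deg * rad
  la1 <- lat * rad
  lo1 <- lon * rad
  la2 <- asin(sin(la1) * cos(d) + cos(la1) * sin(d) * cos(br))
  lo2 <- lo1 + atan2(sin(br) * sin(d) * cos(la1),
                     cos(d) - sin(la1) * sin(la2))
  c(lon = lo2 / rad, lat = la2 / rad)
}
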