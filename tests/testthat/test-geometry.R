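test_that("haversine distance matches closed forms and is metric-like", {
  # one degree of longitude at the equator on the 6371-km sphere
  expect_equal(haversine_km(0, 0, 1, 0), 2 * pi * 6371 / 360, tolerance = 1e-5)
  expect_equal(haversine_km(12.3, 78.9, 12.3, 78.9), 0)
  set.seed(1)
  lon <- runif(100, -180, 180)
  lat <- runif(100, -89, 89)
  lon2 <- runif(100, -180, 180)
  lat2 <- runif(100, -89, 89)
  expect_equal(haversine_km(lon, lat, lon2, lat2),
               haversine_km(lon2, lat2, lon, lat))
  # triangle inequality on random triples
  for (i in 1:40) {
    p <- cbind(runif(3, -180, 180), runif(3, -85, 85))
    d12 <- haversine_km(p[1, 1], p[1, 2], p[2, 1], p[2, 2])
    d23 <- haversine_km(p[2, 1], p[2, 2], p[3, 1], p[3, 2])
    d13 <- haversine_km(p[1, 1], p[1, 2], p[3, 1], p[3, 2])
    expect_lte(d13, d12 + d23 + 1e-9)
  }
  expect_error(haversine_km(NA, 0, 1, 0), "finite")
  expect_error(haversine_km(0, 95, 1, 0), "coordinates")
})

test_that("haversine agrees with an independent great-circle implementation", {
  set.seed(2)
  a <- cbind(runif(50, -180, 180), runif(50, -85, 85))
  b <- cbind(runif(50, -180, 180), runif(50, -85, 85))
  ours <- haversine_km(a[, 1], a[, 2], b[, 1], b[, 2])
  ref <- geosphere::distHaversine(a, b, r = 6371000) / 1000
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("point-in-polygon follows the even-odd rule with boundary inside", {
  expect_true(point_in_polygon(0.5, 0.5, unit_square))
  expect_false(point_in_polygon(10, 10, unit_square))
  expect_true(point_in_polygon(0, 0, unit_square))   # vertex
  expect_true(point_in_polygon(0.5, 0, unit_square)) # edge
  expect_error(point_in_polygon(0, 0, unit_square[c(1, 2, 1), ]), "degenerate")
})

test_that("trip classification needs a single strictly-outside fix", {
  area <- tiny_area()
  inside <- make_fixes(0:19 * 10, lon = runif(20, 0.2, 0.8), lat = runif(20, 0.2, 0.8))
  expect_identical(classify_trip(inside, area), "inside")
  one_out <- inside
  one_out$lon[7] <- -0.4
  expect_identical(classify_trip(one_out, area), "outside")
  # order of fixes is irrelevant
  shuffled <- one_out[sample(nrow(one_out)), ]
  expect_identical(classify_trip(shuffled, area), "outside")
  # a fix exactly on the ring stays inside
  on_ring <- inside
  on_ring$lon[3] <- 0
  expect_identical(classify_trip(on_ring, area), "inside")
  expect_error(classify_trip(inside[0, ], area), "no fixes")
})

test_that("classification is invariant to rotation of the ring vertices", {
  area <- tiny_area()
  fx <- make_fixes(c(0, 10, 20), lon = c(0.5, 1.4, 0.5), lat = c(0.5, 0.5, 0.6))
  lab <- classify_trip(fx, area)
  ring <- unit_square[1:4, ]
  for (shift in 1:3) {
    rot <- ring[c((shift + 1):4, 1:shift), , drop = FALSE]
    area2 <- study_area(rot, area$land, area$colonies)
    expect_identical(classify_trip(fx, area2), lab)
  }
})

test_that("study areas round-trip through GeoJSON", {
  area <- tiny_area()
  path <- tempfile(fileext = ".geojson")
  write_study_area(area, path)
  back <- read_study_area(path)
  expect_equal(back$colonies$C1, area$colonies$C1)
  expect_true(point_in_polygon(0.5, 0.5, back$fjord))
  expect_length(back$land, 1)
  expect_error(study_area(unit_square, colonies = list(C = c(5, 5))), "outside")
})
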