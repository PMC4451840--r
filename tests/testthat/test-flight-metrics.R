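test_that("geodesic distance matches ellipsoid anchors and is a metric", {
  expect_equal(geodesic_distance(c(-16.6, 28.3), c(-16.6, 28.3)), 0)
  ## 0.01 deg of latitude at the equator: WGS84 meridian arc = 1105.74 m
  expect_equal(geodesic_distance(c(0, 0), c(0, 0.01)), 1105.74,
               tolerance = 0.01 / 1105.74)
  set.seed(8)
  for (i in 1:50) {
    p <- cbind(runif(3, -17, -16), runif(3, 28, 29))
    ab <- geodesic_distance(p[1, ], p[2, ])
    bc <- geodesic_distance(p[2, ], p[3, ])
    ac <- geodesic_distance(p[1, ], p[3, ])
    expect_lte(ac, ab + bc + 1e-6)
  }
  expect_error(geodesic_distance(c(0, 10), c(180, -10)), "antipodal")
  expect_error(geodesic_distance(c(0, 95), c(1, 1)), "range")
})

test_that("a track-centred local projection agrees with the ellipsoid within 0.1%", {
  set.seed(12)
  lon0 <- -16.6; lat0 <- 28.3
  for (i in 1:40) {
    p <- c(lon0 + runif(1, -0.3, 0.3), lat0 + runif(1, -0.3, 0.3))
    q <- c(lon0 + runif(1, -0.3, 0.3), lat0 + runif(1, -0.3, 0.3))
    geo <- geodesic_distance(p, q)
    if (geo < 100) next
    mid <- (p[2] + q[2]) / 2
    m_lat <- m_per_deg_lat_at(mid)
    m_lon <- (111412.84 * cos(mid * pi / 180) -
                93.5 * cos(3 * mid * pi / 180) +
                0.118 * cos(5 * mid * pi / 180))
    dx <- (q[1] - p[1]) * m_lon
    dy <- (q[2] - p[2]) * m_lat
    expect_lt(abs(sqrt(dx^2 + dy^2) - geo) / geo, 0.001)
  }
})

test_that("apparent sunset matches an independent ephemeris within 2 minutes", {
  ## study-area coordinates across the year, incl. the fledging season
  cases <- expand.grid(date = as.Date(c("2013-10-25", "2014-10-30",
                                        "2013-03-20", "2013-06-21",
                                        "2013-12-21")),
                       lon = c(-16.5), lat = c(28.3))
  for (i in seq_len(nrow(cases))) {
    s <- apparent_sunset(cases$date[i], cases$lon[i], cases$lat[i])
    mins <- as.numeric(difftime(s$sunset_utc,
                                as.POSIXct(cases$date[i], tz = "UTC"),
                                units = "mins"))
    oracle <- spencer_sunset_min(cases$date[i], cases$lon[i], cases$lat[i])
    expect_lt(abs(mins - oracle), 2)
  }
})

test_that("equinox sunset at the equator is near 18:00 local apparent time", {
  s <- apparent_sunset("2013-03-20", 0, 0)
  mins_utc <- as.numeric(difftime(s$sunset_utc,
                                  as.POSIXct("2013-03-20", tz = "UTC"),
                                  units = "mins"))
  ## local apparent time = UTC + equation of time (lon = 0)
  eqt <- 229.18 * (0.000075 + 0.001868 * cos(2 * pi * 78 / 365) -
                     0.032077 * sin(2 * pi * 78 / 365) -
                     0.014615 * cos(4 * pi * 78 / 365) -
                     0.040849 * sin(4 * pi * 78 / 365))
  expect_lt(abs(mins_utc + eqt - 18 * 60), 10)
})

test_that("sunset gets later as one moves west and rejects polar latitudes", {
  lons <- seq(-14, -18, by = -1)
  mins <- vapply(lons, function(lo)
    as.numeric(difftime(apparent_sunset("2013-10-25", lo, 28.3)$sunset_utc,
                        as.POSIXct("2013-10-25", tz = "UTC"),
                        units = "mins")), numeric(1))
  expect_true(all(diff(mins) > 0))
  expect_error(apparent_sunset("2013-10-25", 0, 70), "polar")
})

test_that("tortuosity spans its closed forms: straight, loop, half", {
  sun <- as.POSIXct("2013-10-25 18:27:00", tz = "UTC")
  ## straight two-fix track: S = L so T = 0
  s <- summarize_flight(straight_track(2), sun)
  expect_equal(s$tortuosity, 0)
  ## closed loop: S = 0, L > 0, T = 1
  t0 <- as.POSIXct("2013-10-25 20:00:00", tz = "UTC")
  loop <- track("loop", data.frame(
    time = t0 + c(0, 30, 60),
    lon = c(-16.6, -16.6, -16.6), lat = c(28.25, 28.26, 28.25),
    altitude = 50))
  expect_equal(summarize_flight(loop, sun)$tortuosity, 1)
  ## out-and-back half: L = 1000 m, S = 500 m, T = 0.5
  dlat <- 1 / m_per_deg_lat_at(28.25)   # 1 m in degrees of latitude here
  half <- track("half", data.frame(
    time = t0 + c(0, 30, 60),
    lon = rep(-16.6, 3), lat = 28.25 + c(0, 750, 500) * dlat,
    altitude = 50))
  s <- summarize_flight(half, sun)
  expect_equal(s$tortuosity, 0.5, tolerance = 1e-6)
  expect_equal(s$length_m, 1000, tolerance = 1e-3)
  expect_equal(s$straight_length_m, 500, tolerance = 1e-3)
})

test_that("timing, duration and speed are consistent with the fix record", {
  sun <- as.POSIXct("2013-10-25 18:27:00", tz = "UTC")
  tr <- straight_track(11, step_m = 373, dt_s = 30)   # ~44.8 km/h
  s <- summarize_flight(tr, sun)
  expect_equal(s$timing_min, 93)             # 20:00 departure
  expect_equal(s$duration_min, 5)
  ## speed x duration reproduces the path length within 0.1%
  expect_lt(abs(s$speed_kmh * s$duration_min / 60 * 1000 - s$length_m) /
              s$length_m, 0.001)
  ## pre-sunset departures are kept and reported
  early <- straight_track(3)
  expect_message(
    s2 <- summarize_flight(early, as.POSIXct("2013-10-25 21:00:00",
                                             tz = "UTC")),
    "before sunset")
  expect_equal(s2$timing_min, -60)
})

test_that("speed is truncated at the first on-water rest", {
  ## grid: northern half sea (NA), southern half land at 100 m
  m <- matrix(100, 40, 40); m[1:20, ] <- NA
  dem <- metric_grid(m, cell_m = 100, kind = "elevation_m")
  t0 <- as.POSIXct("2013-10-25 20:00:00", tz = "UTC")
  lat_land <- dem$y_origin - 39.5 * dem$cell_size   # deep in the land half
  dlat <- 1 / m_per_deg_lat_at(lat_land)
  ## 4 fast fixes north (~37 km/h), then two slow drifting fixes on the sea
  lat <- lat_land + c(0, 310, 620, 3200, 3210, 3220) * dlat
  tr <- track("r1", data.frame(time = t0 + c(0, 30, 60, 300, 600, 900),
                               lon = rep(dem$x_origin + 20 * dem$cell_size, 6),
                               lat = lat, altitude = 10))
  s_rest <- summarize_flight(tr, t0 - 3600, dem = dem)
  s_full <- summarize_flight(tr, t0 - 3600)
  expect_lt(s_full$speed_kmh, s_rest$speed_kmh)  # drift drags the mean down
  ## rest detected at the 5th fix: 3210 m flown in 600 s
  expect_equal(s_rest$speed_kmh, 3.210 / (600 / 3600), tolerance = 1e-3)
})

test_that("dropping interior fixes never lengthens the path", {
  set.seed(3)
  t0 <- as.POSIXct("2013-10-25 20:00:00", tz = "UTC")
  for (i in 1:20) {
    n <- sample(4:12, 1)
    fx <- data.frame(time = t0 + (0:(n - 1)) * 30,
                     lon = -16.6 + cumsum(rnorm(n, 0, 0.002)),
                     lat = 28.25 + cumsum(rnorm(n, 0, 0.002)),
                     altitude = 50)
    tr <- track(sprintf("p%d", i), fx)
    keep <- sort(c(1, sample(2:(n - 1), max(1, n - 4)), n))
    sub <- track("sub", fx[keep, ])
    sun <- t0 - 3600
    expect_lte(summarize_flight(sub, sun)$length_m,
               summarize_flight(tr, sun)$length_m + 1e-6)
    ## invariant: S <= L hence T in [0, 1]
    s <- summarize_flight(tr, sun)
    expect_lte(s$straight_length_m, s$length_m + 1e-6)
    expect_gte(s$tortuosity, 0); expect_lte(s$tortuosity, 1)
  }
})

test_that("colony-to-rescue straight distance anchors", {
  expect_equal(straight_distance_colony_to_rescue(c(-16.6, 28.3),
                                                  c(-16.6, 28.3)), 0)
  d <- straight_distance_colony_to_rescue(
    c(-16.6, 28.3), c(-16.6, 28.3 + 3000 / m_per_deg_lat_at(28.3135)))
  expect_lt(abs(d - 3000), 3)
})
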