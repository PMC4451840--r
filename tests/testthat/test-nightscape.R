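test_that("island generation is deterministic and dark without lights", {
  cfg <- nightscape_config(island_radius_m = 3000, dem_cell_m = 150,
                           n_lights = 10, seed = 11)
  a <- make_island(cfg); b <- make_island(cfg)
  expect_identical(a$dem$values, b$dem$values)
  expect_identical(a$radiance$values, b$radiance$values)
  expect_identical(a$lights, b$lights)

  dark <- make_island(nightscape_config(island_radius_m = 3000,
                                        dem_cell_m = 150, n_lights = 0,
                                        background_radiance = 0, seed = 11))
  land <- !is.na(dark$dem$values)
  expect_true(all(dark$radiance$values[land] == 0))
  ## DEM structure: elevation 0-ish at coast, peak near centre, sea is nodata
  expect_true(any(is.na(dark$dem$values)))
  expect_gt(max(dark$dem$values, na.rm = TRUE), 3000)
})

test_that("point-light kernel matches direct Gaussian evaluation", {
  geom <- metric_grid(matrix(0, 41, 41), cell_m = 100)
  ctr <- c(geom$x_origin + 20.5 * geom$cell_size,
           geom$y_origin - 20.5 * geom$cell_size)
  A <- 50; sig <- 300
  rad <- render_radiance(geom, data.frame(lon = ctr[1], lat = ctr[2],
                                          amplitude = A),
                         sigma_m = sig, background = 0)
  expect_equal(which(rad$values == max(rad$values), arr.ind = TRUE)[1, ],
               c(row = 21L, col = 21L))
  expect_equal(rad$values[21, 21], A, tolerance = 1e-6)
  ## closed-form oracle along the central row: A exp(-x^2 / (2 sigma^2))
  ## with x the east-west offset of each cell centre from the light
  ## (published parallel-arc series for metres per degree of longitude)
  row_vals <- rad$values[21, ]
  lon_c <- geom$x_origin + (seq_len(41) - 0.5) * geom$cell_size
  phi <- 28.3 * pi / 180
  m_lon <- 111412.84 * cos(phi) - 93.5 * cos(3 * phi) + 0.118 * cos(5 * phi)
  x_m <- (lon_c - ctr[1]) * m_lon
  oracle <- A * exp(-x_m^2 / (2 * sig^2))
  expect_equal(row_vals, oracle, tolerance = 1e-3)
  ## monotone decay with distance from the light
  half <- row_vals[21:41]
  expect_true(all(diff(half) <= 0))
})

test_that("colonies land below the elevation ceiling, reproducibly", {
  isl <- test_island()
  col <- place_colonies(isl$dem, 6, max_elevation_m = 1000, seed = 3)
  expect_equal(nrow(col), 6L)
  expect_true(all(col$elevation_m > 0 & col$elevation_m <= 1000))
  ## every centre on land
  expect_true(all(!is.na(sample_point(isl$dem, col$lon, col$lat))))
  expect_identical(col, place_colonies(isl$dem, 6, max_elevation_m = 1000,
                                       seed = 3))
  expect_equal(nrow(place_colonies(isl$dem, 0)), 0L)
  expect_error(place_colonies(isl$dem, 3, max_elevation_m = -5), "no land")
})

test_that("departure offsets follow the zero-truncated normal law", {
  cfg <- flight_config()
  sunset <- as.POSIXct("2013-10-25 18:27:00", tz = "UTC")
  dep <- simulate_departure(cfg, sunset, 10000, seed = 2)
  offs <- as.numeric(difftime(dep, sunset, units = "mins"))
  expect_true(all(offs > 0))
  ## the realised moments of the truncated law match the published sample
  ## statistics (161.2 +/- 153.8 min after sunset)
  expect_lt(abs(mean(offs) - 161.2), 3 * 153.8 / sqrt(10000))
  expect_lt(abs(sd(offs) - 153.8), 6)
  ## moment identity oracle: the sampled parent, re-truncated analytically,
  ## must reproduce the configured mean
  par_mu <- fallout:::truncnorm_parent(161.2, 153.8)
  a <- -par_mu[1] / par_mu[2]
  lambda <- dnorm(a) / (1 - pnorm(a))
  expect_equal(par_mu[1] + par_mu[2] * lambda, 161.2, tolerance = 1e-4)
  ## most fledglings leave within the first three hours after sunset
  expect_gt(mean(offs <= 180), 0.5)

  dep0 <- simulate_departure(flight_config(departure_sd_min = 0), sunset, 5)
  expect_true(all(as.numeric(difftime(dep0, sunset, units = "mins")) == 161.2))
  expect_error(flight_config(departure_sd_min = -1), "SD")
})

test_that("degenerate flight configurations behave as expected", {
  isl <- test_island(); col <- test_colonies()
  start <- c(col$lon[1], col$lat[1])
  ## fully persistent, light-blind bird flies straight to the sea
  fl <- simulate_flight(start, isl$dem, isl$radiance,
                        flight_config(persistence = 1,
                                      light_attraction_weight = 0,
                                      seaward_weight = 0,
                                      grounding_hazard_scale = 0, seed = 5))
  expect_equal(fl$outcome, "reached_sea")
  s <- summarize_flight(fl$track, as.POSIXct("2013-10-25 18:27:00",
                                             tz = "UTC"))
  expect_lt(s$tortuosity, 0.05)
  ## zero hazard: everyone reaches the sea
  fc0 <- flight_config(grounding_hazard_scale = 0, seed = 5)
  sun <- as.POSIXct("2013-10-25 18:27:00", tz = "UTC")
  coh <- simulate_cohort(12, col, isl$dem, isl$radiance, fc0, sun, seed = 5)
  expect_true(all(coh$birds$outcome == "reached_sea"))
  ## starting at sea is rejected
  expect_error(simulate_flight(c(isl$dem$x_origin + isl$dem$cell_size,
                                 isl$dem$y_origin - isl$dem$cell_size),
                               isl$dem, isl$radiance, fc0), "land")
})

test_that("cohorts are seed-stable and extending one never rewrites history", {
  isl <- test_island(); col <- test_colonies()
  fc <- flight_config(seed = 9)
  sun <- as.POSIXct("2013-10-25 18:27:00", tz = "UTC")
  a <- simulate_cohort(6, col, isl$dem, isl$radiance, fc, sun, seed = 9)
  b <- simulate_cohort(6, col, isl$dem, isl$radiance, fc, sun, seed = 9)
  expect_identical(a$birds, b$birds)
  big <- simulate_cohort(9, col, isl$dem, isl$radiance, fc, sun, seed = 9)
  expect_identical(big$birds[1:6, c("bird_id", "outcome", "ground_lon")],
                   a$birds[, c("bird_id", "outcome", "ground_lon")])
})

test_that("colony outcomes are binomial with the configured logit model", {
  ## slopes 0, plogis(beta0) = 0.14: pooled recovery converges to 14%
  b0 <- qlogis(0.14)
  colonies <- data.frame(distance_to_sea_m = runif(400, 0, 5000),
                         elevation_m = runif(400, 0, 1000))
  out <- simulate_colony_outcomes(colonies,
                                  grounding_config(beta0 = b0,
                                                   beta_distance_per_m = 0,
                                                   beta_elevation_per_m = 0),
                                  n_banded = 50, seed = 21)
  rate <- sum(out$n_recovered) / sum(out$n_banded)
  expect_lt(abs(rate - 0.14), 3 * sqrt(0.14 * 0.86 / 20000))
  expect_true(all(out$n_recovered <= out$n_banded))

  zero <- simulate_colony_outcomes(colonies[1:5, ], grounding_config(),
                                   n_banded = 0, seed = 1)
  expect_true(all(zero$n_recovered == 0))
  expect_identical(out$n_recovered,
                   simulate_colony_outcomes(colonies,
                                            grounding_config(beta0 = b0,
                                                             beta_distance_per_m = 0,
                                                             beta_elevation_per_m = 0),
                                            n_banded = 50,
                                            seed = 21)$n_recovered)
})

test_that("generated layers survive the file round trip (validator property)", {
  isl <- test_island()
  f1 <- withr::local_tempfile(fileext = ".asc")
  f2 <- withr::local_tempfile(fileext = ".asc")
  write_raster(isl$dem, f1); write_raster(isl$radiance, f2)
  expect_identical(read_raster(f1, kind = "elevation_m")$values,
                   isl$dem$values)
  expect_identical(read_raster(f2)$values, isl$radiance$values)
})
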