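test_that("point sampling follows the half-open cell convention", {
  g <- metric_grid(matrix(7, 4, 4))
  inside <- cell_centre_pts <- expand.grid(
    lon = g$x_origin + c(0.2, 2.7) * g$cell_size,
    lat = g$y_origin - c(0.4, 3.1) * g$cell_size)
  expect_true(all(sample_point(g, inside$lon, inside$lat) == 7))

  m <- matrix(as.numeric(1:16), 4, 4, byrow = TRUE)
  g <- metric_grid(m)
  ## point exactly on the shared corner of cells (1:2, 1:2): lower-right wins
  lon <- g$x_origin + 1 * g$cell_size
  lat <- g$y_origin - 1 * g$cell_size
  expect_equal(sample_point(g, lon, lat), m[2, 2])
  expect_error(sample_point(g, g$x_origin - 1, lat), "outside")
})

test_that("point sampling equals brute-force row/column arithmetic", {
  set.seed(4)
  m <- matrix(runif(15 * 11), 15, 11)
  g <- metric_grid(m, cell_m = 80)
  lon <- g$x_origin + runif(300, 0, 11) * g$cell_size
  lat <- g$y_origin - runif(300, 0, 15) * g$cell_size
  got <- sample_point(g, lon, lat)
  oracle <- vapply(seq_along(lon), function(i) {
    cc <- floor((lon[i] - g$x_origin) / g$cell_size) + 1
    rr <- floor((g$y_origin - lat[i]) / g$cell_size) + 1
    m[rr, cc]
  }, numeric(1))
  expect_identical(got, oracle)
})

test_that("track exposure collects the traversed cells", {
  g <- metric_grid(matrix(3.5, 6, 6))
  t0 <- as.POSIXct("2013-10-25 20:00:00", tz = "UTC")
  within <- track("w", data.frame(
    time = t0 + c(0, 30),
    lon = g$x_origin + c(2.2, 2.8) * g$cell_size,
    lat = g$y_origin - c(3.3, 3.6) * g$cell_size, altitude = 10))
  e <- sample_track(g, within)
  expect_equal(e$mean_radiance, 3.5); expect_equal(e$max_radiance, 3.5)
  expect_equal(e$n_cells, 1L)

  m <- matrix(0, 3, 3); m[2, ] <- c(1, 2, 3)
  g <- metric_grid(m)
  horiz <- track("h", data.frame(
    time = t0 + c(0, 30),
    lon = g$x_origin + c(0.2, 2.9) * g$cell_size,
    lat = rep(g$y_origin - 1.5 * g$cell_size, 2), altitude = 10))
  e <- sample_track(g, horiz)
  expect_equal(e$mean_radiance, 2); expect_equal(e$max_radiance, 3)
  expect_equal(e$n_cells, 3L)
})

test_that("grid-walk cell sets match a 1/20-cell super-sampling oracle", {
  set.seed(17)
  t0 <- as.POSIXct("2013-10-25 20:00:00", tz = "UTC")
  for (i in 1:200) {
    nr <- sample(4:9, 1); nc <- sample(4:9, 1)
    g <- metric_grid(matrix(runif(nr * nc), nr, nc), cell_m = 50)
    p <- c(runif(1, 0.05, nc - 0.05), runif(1, 0.05, nr - 0.05))
    q <- c(runif(1, 0.05, nc - 0.05), runif(1, 0.05, nr - 0.05))
    tr <- track("s", data.frame(
      time = t0 + c(0, 30),
      lon = g$x_origin + c(p[1], q[1]) * g$cell_size,
      lat = g$y_origin - c(p[2], q[2]) * g$cell_size, altitude = 10))
    cells <- supersample_cells(g, tr$fixes$lon[1], tr$fixes$lat[1],
                               tr$fixes$lon[2], tr$fixes$lat[2])
    vals <- g$values[cells]
    e <- sample_track(g, tr)
    expect_equal(e$mean_radiance, mean(vals), tolerance = 1e-12)
    expect_equal(e$max_radiance, max(vals), tolerance = 1e-12)
    expect_equal(e$n_cells, nrow(cells))
  }
})

test_that("buffer statistics: uniform, counting oracle, degenerate radius", {
  g <- metric_grid(matrix(4.25, 30, 30), cell_m = 100)
  ctr <- c(g$x_origin + 15 * g$cell_size, g$y_origin - 15 * g$cell_size)
  b <- buffer_stats(g, ctr, 800)
  expect_equal(b$mean, 4.25); expect_equal(b$max, 4.25)

  m <- matrix(0, 31, 31); m[16, 16] <- 60
  g <- metric_grid(m, cell_m = 100)
  ctr <- c(g$x_origin + 15.5 * g$cell_size, g$y_origin - 15.5 * g$cell_size)
  b <- buffer_stats(g, ctr, 550)
  ## counting oracle: cells with centre within 550 m of the bright centre
  cc <- expand.grid(r = 1:31, c = 1:31)
  n_in <- sum(sqrt((abs(cc$c - 16) * 100 * cos(28.3 * pi / 180))^2 +
                     (abs(cc$r - 16) * 100)^2) <= 550)
  expect_equal(b$n_cells, n_in)
  expect_equal(b$max, 60)
  expect_equal(b$mean, 60 / n_in)

  tiny <- buffer_stats(g, ctr, 10)   # radius far below half a cell
  expect_equal(tiny$n_cells, 1L)
  expect_equal(tiny$mean, 60)
})

test_that("distance to sea: adjacency, island radius and inland monotonicity", {
  ## 1-cell sea rim around a land block, 25 m cells
  m <- matrix(NA_real_, 9, 9); m[2:8, 2:8] <- 50
  dem <- metric_grid(m, cell_m = 25, kind = "elevation_m")
  p_lon <- dem$x_origin + 4.5 * dem$cell_size   # land cell (2, 5), adjacent
  p_lat <- dem$y_origin - 1.5 * dem$cell_size   # to the northern sea rim
  expect_equal(distance_to_sea(dem, p_lon, p_lat), 25, tolerance = 0.02)

  isl <- test_island()
  centre_lon <- isl$dem$x_origin + isl$dem$n_cols / 2 * isl$dem$cell_size
  centre_lat <- isl$dem$y_origin - isl$dem$n_rows / 2 * isl$dem$cell_size
  d_centre <- distance_to_sea(isl$dem, centre_lon, centre_lat)
  expect_lt(abs(d_centre - 6000), 150)   # island radius within a cell or two

  ## moving inland along a radial line never decreases the distance
  lats <- centre_lat - seq(5500, 500, by = -500) / 111132.9
  d <- distance_to_sea(isl$dem, rep(centre_lon, length(lats)), lats)
  expect_true(all(diff(d) >= -1))

  sea_lon <- isl$dem$x_origin + 1.5 * isl$dem$cell_size
  sea_lat <- isl$dem$y_origin - 1.5 * isl$dem$cell_size
  expect_warning(d0 <- distance_to_sea(isl$dem, sea_lon, sea_lat),
                 "over sea")
  expect_equal(d0, 0)
})

test_that("burrow clustering implements the 1-km single-linkage rule", {
  mk <- function(lat_offsets_m, lon = -16.6) {
    data.frame(burrow_id = sprintf("b%d", seq_along(lat_offsets_m)),
               lon = lon, lat = 28.3 + lat_offsets_m / 111132.9,
               n_banded = 5, n_recovered = 1)
  }
  expect_equal(nrow(cluster_burrows(mk(c(0, 80)))), 1L)
  expect_equal(nrow(cluster_burrows(mk(c(0, 1500)))), 2L)
  ## chaining: 0, 900, 1800 m are one colony under single linkage
  chain <- cluster_burrows(mk(c(0, 900, 1800)))
  expect_equal(nrow(chain), 1L)
  expect_equal(chain$n_banded, 15)
  ## brute-force connected-components oracle on random layouts
  set.seed(23)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    b <- mk(runif(n, 0, 4000))
    cl <- cluster_burrows(b)
    d <- as.matrix(dist(b$lat * 111132.9))
    adj <- d <= 1000
    comp <- seq_len(n)
    repeat {
      new <- apply(adj, 1, function(a) min(comp[a]))
      if (all(new == comp)) break
      comp <- new
    }
    expect_equal(nrow(cl), length(unique(comp)))
  }
})

test_that("colony partition is invariant to burrow input order", {
  set.seed(31)
  b <- data.frame(burrow_id = sprintf("b%02d", 1:12),
                  lon = -16.6 + runif(12, 0, 0.04),
                  lat = 28.3 + runif(12, 0, 0.04),
                  n_banded = rpois(12, 6), n_recovered = 0)
  a <- cluster_burrows(b)
  perm <- cluster_burrows(b[sample(12), ])
  expect_equal(a$centre_lon, perm$centre_lon)
  expect_equal(a$n_banded, perm$n_banded)
  expect_identical(a$members, perm$members)
})

test_that("colony covariates satisfy the buffer inclusion invariant", {
  isl <- test_island()
  col <- test_colonies()
  cov <- colony_covariates(
    data.frame(colony_id = col$colony_id, centre_lon = col$lon,
               centre_lat = col$lat), isl$dem, isl$radiance)
  expect_true(all(cov$radiance_at_colony <= cov$radiance_max_3km + 1e-12))
  expect_true(all(cov$radiance_mean_3km <= cov$radiance_max_3km + 1e-12))
  expect_true(all(cov$distance_to_sea_m >= 0))
})
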