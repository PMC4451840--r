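## Shared fixtures, all built in code.

## A small raster in "metric degrees": cell edge ~cell_m metres at lat0.
metric_grid <- function(values, cell_m = 100, lon0 = -16.6, lat0 = 28.3,
                        kind = "radiance_nW_sr_cm2") {
  cs <- cell_m / 111132.9
  raster_grid(values, x_origin = lon0, y_origin = lat0, cell_size = cs,
              kind = kind)
}

## Straight track due north from (lon, lat): n fixes, step_m apart, dt_s apart.
straight_track <- function(n = 5, step_m = 300, dt_s = 30,
                           lon = -16.6, lat = 28.25, bird = "t1",
                           group = "first_flight") {
  dlat <- step_m / 111132.9
  track(bird, data.frame(
    time = as.POSIXct("2013-10-25 20:00:00", tz = "UTC") + (0:(n - 1)) * dt_s,
    lon = rep(lon, n), lat = lat + (0:(n - 1)) * dlat,
    altitude = 50), group = group)
}

## Memoised small synthetic island (coarse cells keep unit tests fast).
test_island <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_island(nightscape_config(
        island_radius_m = 6000, dem_cell_m = 100, n_lights = 25, seed = 42))
    cache
  }
})

test_colonies <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      isl <- test_island()
      cache <<- place_colonies(isl$dem, 8, seed = 42,
                               min_separation_m = 800)
    }
    cache
  }
})

## Meridian-arc oracle: WGS84 metres per degree of latitude (published
## trigonometric series, independent of the package's projection code).
m_per_deg_lat_at <- function(lat) {
  111132.92 - 559.82 * cos(2 * lat * pi / 180) +
    1.175 * cos(4 * lat * pi / 180) - 0.0023 * cos(6 * lat * pi / 180)
}

## Independent low-precision solar ephemeris (Spencer 1971 Fourier series):
## a different algorithm from the implementation, used as sunset oracle.
spencer_sunset_min <- function(date, lon, lat) {
  doy <- as.integer(strftime(date, "%j"))
  g <- 2 * pi * (doy - 1) / 365
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  eqt <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                     0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  phi <- lat * pi / 180
  ha <- acos(cos(90.833 * pi / 180) / (cos(phi) * cos(decl)) -
               tan(phi) * tan(decl))
  720 - 4 * lon - eqt + 4 * ha * 180 / pi
}

## Brute-force traversed-cell oracle, independent of the package's grid
## walk: take a dense uniform super-sample of the segment plus the midpoint
## of every span between consecutive grid-line crossings (so that even
## sliver clips shorter than the sampling step are caught exactly).
supersample_cells <- function(grid, lon1, lat1, lon2, lat2) {
  u1 <- (lon1 - grid$x_origin) / grid$cell_size
  u2 <- (lon2 - grid$x_origin) / grid$cell_size
  v1 <- (grid$y_origin - lat1) / grid$cell_size
  v2 <- (grid$y_origin - lat2) / grid$cell_size
  t <- seq(0, 1, by = 1 / (20 * max(1, ceiling(abs(u2 - u1) + abs(v2 - v1)))))
  cross <- numeric(0)
  if (u2 != u1) {
    ks <- seq(ceiling(min(u1, u2)), floor(max(u1, u2)))
    cross <- c(cross, (ks - u1) / (u2 - u1))
  }
  if (v2 != v1) {
    ks <- seq(ceiling(min(v1, v2)), floor(max(v1, v2)))
    cross <- c(cross, (ks - v1) / (v2 - v1))
  }
  brk <- sort(unique(c(0, 1, cross[cross > 0 & cross < 1])))
  t <- sort(unique(c(t, (brk[-1] + brk[-length(brk)]) / 2)))
  u <- u1 + t * (u2 - u1); v <- v1 + t * (v2 - v1)
  unique(cbind(row = floor(v) + 1, col = floor(u) + 1))
}

## Independent randomisation-test oracle: enumerate every size-n1 subset of
## the pooled data by bitmask (a different enumeration than the
## implementation's combn route).
brute_perm_p <- function(x, y, tail = "two_sided") {
  pooled <- c(x, y); n <- length(pooled); n1 <- length(x)
  obs <- mean(x) - mean(y)
  hits <- 0L; total <- 0L
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(idx) != n1) next
    total <- total + 1L
    s <- mean(pooled[idx]) - mean(pooled[-idx])
    hit <- switch(tail,
                  two_sided = abs(s) >= abs(obs) - 1e-9,
                  greater = s >= obs - 1e-9,
                  less = s <= obs + 1e-9)
    if (hit) hits <- hits + 1L
  }
  hits / total
}

## grounding distances (m) of a simulated cohort, bird-wise
grounding_distances <- function(cohort, colonies) {
  g <- cohort$birds[cohort$birds$outcome == "grounded", ]
  if (nrow(g) == 0) return(numeric(0))
  vapply(seq_len(nrow(g)), function(i) {
    cl <- colonies[colonies$colony_id == g$colony_id[i], ]
    geodesic_distance(c(cl$lon, cl$lat), c(g$ground_lon[i], g$ground_lat[i]))
  }, numeric(1))
}
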