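#' Synthetic nightscape configuration
#'
#' Parameters of the synthetic island generator. Defaults emulate a large,
#' steep Atlantic island with an intensely lit coastal ring: peak elevation
#' 3718 m, 25 m DEM cells, and maximum coastal radiance 103.6 nW/(sr cm^2)
#' clipped at the brightest urban pixels.
#'
#' @param island_radius_m radius of the (roughly circular) island coastline.
#' @param peak_elevation_m summit elevation of the central volcano.
#' @param dem_cell_m DEM cell edge, metres (converted internally to degrees).
#' @param n_lights number of coastal point lights.
#' @param light_intensity_max radiance ceiling, nW/(sr cm^2).
#' @param light_kernel_sigma_m Gaussian spread of each light, metres.
#' @param background_radiance dark-sky background radiance, nW/(sr cm^2).
#' @param profile_exponent shape of the radial elevation profile
#'   `peak * (1 - d/R)^profile_exponent`; values above 1 give the convex
#'   shield-volcano profile of a large oceanic island, so the low-elevation
#'   nesting band (below 1000 m) extends several km inland.
#' @param centre_lon,centre_lat island centre, degrees WGS84.
#' @param seed integer RNG seed for light placement and terrain noise.
#' @return list of class `nightscape_config`.
#' @export
nightscape_config <- function(island_radius_m = 12000,
                              peak_elevation_m = 3718,
                              dem_cell_m = 25,
                              n_lights = 60,
                              light_intensity_max = 103.6,
                              light_kernel_sigma_m = 400,
                              background_radiance = 0.25,
                              profile_exponent = 1.8,
                              centre_lon = -16.6, centre_lat = 28.3,
                              seed = 1L) {
  stopifnot(island_radius_m > 0, peak_elevation_m > 0, dem_cell_m > 0,
            light_kernel_sigma_m > 0, light_intensity_max >= 0,
            background_radiance >= 0)
  if (n_lights < 0) stop("n_lights must be >= 0")
  structure(as.list(environment()), class = "nightscape_config")
}


#' Generate a synthetic island: DEM and nocturnal radiance
#'
#' The DEM is a noisy radial cone: elevation 0 at the coastline rising to
#' `peak_elevation_m` at the centre, with smooth multiplicative terrain noise;
#' sea cells (beyond the coastline) are nodata. The radiance layer is the
#' dark-sky background plus Gaussian-kernel point lights placed in a coastal
#' ring, clipped to `light_intensity_max`. Both grids share one geotransform.
#'
#' @param config a [nightscape_config()].
#' @return list with `dem` and `radiance` (both [raster_grid()]) and
#'   `lights` (data frame `lon`, `lat`, `amplitude`).
#' @export
make_island <- function(config = nightscape_config()) {
  stopifnot(inherits(config, "nightscape_config"))
  with_seed(config$seed, {
    R <- config$island_radius_m
    cs_deg <- config$dem_cell_m / wgs84_deg_scales(config$centre_lat)$m_lat
    half_m <- R * 1.06
    n <- 2L * as.integer(ceiling(half_m / config$dem_cell_m))
    x0 <- config$centre_lon - (n / 2) * cs_deg
    y0 <- config$centre_lat + (n / 2) * cs_deg
    ctr_lon <- x0 + (seq_len(n) - 0.5) * cs_deg
    ctr_lat <- y0 - (seq_len(n) - 0.5) * cs_deg
    xy <- local_xy(rep(ctr_lon, each = n), rep(ctr_lat, times = n),
                   config$centre_lon, config$centre_lat)
    d <- sqrt(xy$x^2 + xy$y^2)
    theta <- atan2(xy$y, xy$x)
    ## low-frequency angular noise so slopes are not perfectly symmetric
    ph <- stats::runif(3, 0, 2 * pi)
    noise <- 1 + 0.06 * sin(3 * theta + ph[1]) + 0.04 * sin(5 * theta + ph[2]) +
      0.03 * sin(8 * theta + ph[3])
    elev <- config$peak_elevation_m *
      pmax(1 - d / R, 0)^config$profile_exponent * noise
    elev[d >= R] <- NA_real_
    elev[!is.na(elev) & elev <= 0] <- 0.5
    dem <- raster_grid(matrix(elev, n, n), x0, y0, cs_deg,
                       kind = "elevation_m")
    lights <- if (config$n_lights > 0) {
      ang <- stats::runif(config$n_lights, 0, 2 * pi)
      rad <- stats::runif(config$n_lights, 0.82 * R, 0.97 * R)
      amp <- exp(stats::runif(config$n_lights, log(8),
                              log(max(config$light_intensity_max, 8))))
      ll <- local_to_lonlat(rad * cos(ang), rad * sin(ang),
                            config$centre_lon, config$centre_lat)
      data.frame(lon = ll$lon, lat = ll$lat, amplitude = amp)
    } else data.frame(lon = numeric(0), lat = numeric(0),
                      amplitude = numeric(0))
    radiance <- render_radiance(dem, lights, config$light_kernel_sigma_m,
                                config$background_radiance,
                                config$light_intensity_max)
    list(dem = dem, radiance = radiance, lights = lights)
  })
}

#' Render a radiance raster from point lights
#'
#' Radiance at each cell centre is the background plus the sum of isotropic
#' Gaussian kernels `A exp(-d^2 / (2 sigma^2))` over all lights (d the
#' planar distance to the light), clipped to `clip`.
#'
#' @param geom a [raster_grid()] providing the geotransform (values unused).
#' @param lights data frame with `lon`, `lat`, `amplitude`.
#' @param sigma_m kernel scale in metres.
#' @param background background radiance.
#' @param clip radiance ceiling.
#' @return radiance [raster_grid()] on the same grid.
#' @export
render_radiance <- function(geom, lights, sigma_m, background, clip = Inf) {
  n_r <- geom$n_rows; n_c <- geom$n_cols
  vals <- matrix(background, n_r, n_c)
  lat0 <- geom$y_origin - n_r / 2 * geom$cell_size
  lon0 <- geom$x_origin + n_c / 2 * geom$cell_size
  ctr_lon <- geom$x_origin + (seq_len(n_c) - 0.5) * geom$cell_size
  ctr_lat <- geom$y_origin - (seq_len(n_r) - 0.5) * geom$cell_size
  cx <- local_xy(ctr_lon, rep(lat0, n_c), lon0, lat0)$x
  cy <- local_xy(rep(lon0, n_r), ctr_lat, lon0, lat0)$y
  for (k in seq_len(nrow(lights))) {
    l <- local_xy(lights$lon[k], lights$lat[k], lon0, lat0)
    ## outer sum of squared offsets, truncated at 6 sigma for speed
    dx2 <- (cx - l$x)^2; dy2 <- (cy - l$y)^2
    keep_c <- which(dx2 <= (6 * sigma_m)^2)
    keep_r <- which(dy2 <= (6 * sigma_m)^2)
    if (!length(keep_c) || !length(keep_r)) next
    d2 <- outer(dy2[keep_r], dx2[keep_c], `+`)
    vals[keep_r, keep_c] <- vals[keep_r, keep_c] +
      lights$amplitude[k] * exp(-d2 / (2 * sigma_m^2))
  }
  vals <- pmin(vals, clip)
  raster_grid(vals, geom$x_origin, geom$y_origin, geom$cell_size,
              kind = "radiance_nW_sr_cm2")
}

#' Place breeding colonies on the synthetic island
#'
#' Colony centres are sampled uniformly among land cells with elevation in
#' `(0, max_elevation_m]` (the species nests below 1000 m), subject to a
#' minimum pairwise separation so that colonies remain distinct under the
#' 1-km burrow clustering rule.
#'
#' @param dem elevation [raster_grid()].
#' @param n_colonies number of colonies to place.
#' @param max_elevation_m upper elevation bound, metres.
#' @param seed integer RNG seed.
#' @param min_separation_m minimum pairwise separation between centres.
#' @return data frame `colony_id`, `lon`, `lat`, `elevation_m`.
#' @export
place_colonies <- function(dem, n_colonies, max_elevation_m = 1000,
                           seed = 1L, min_separation_m = 1500) {
  if (n_colonies == 0L)
    return(data.frame(colony_id = character(0), lon = numeric(0),
                      lat = numeric(0), elevation_m = numeric(0)))
  ok <- which(!is.na(dem$values) & dem$values > 0 &
                dem$values <= max_elevation_m, arr.ind = TRUE)
  if (nrow(ok) == 0L)
    stop("no land cells with elevation in (0, ", max_elevation_m, "]")
  with_seed(seed, {
    picked <- matrix(numeric(0), 0, 2)
    sel <- integer(0)
    cand <- sample(nrow(ok))
    for (i in cand) {
      ctr <- cell_centre(dem, ok[i, 1], ok[i, 2])
      pt <- c(ctr$lon, ctr$lat)
      if (nrow(picked) == 0L ||
          min(geosphere::distGeo(picked, pt)) >= min_separation_m) {
        picked <- rbind(picked, pt)
        sel <- c(sel, i)
        if (length(sel) == n_colonies) break
      }
    }
    if (length(sel) < n_colonies)
      stop("could not place ", n_colonies, " colonies ",
           min_separation_m, " m apart; placed ", length(sel))
    data.frame(colony_id = sprintf("colony_%02d", seq_along(sel)),
               lon = dem$x_origin + (ok[sel, 2] - 0.5) * dem$cell_size,
               lat = dem$y_origin - (ok[sel, 1] - 0.5) * dem$cell_size,
               elevation_m = dem$values[ok[sel, , drop = FALSE]])
  })
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed %% 2147483646L))
  expr
}

## Per-bird substream seed: adding birds never perturbs earlier birds.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(index)) %% 2147483646) + 1L
}
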