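#' Summarise one flight
#'
#' Computes the per-flight variables used to compare first and second
#' flights: timing relative to apparent sunset, duration, cumulative path
#' length L, straight (start-to-end) length S, tortuosity `T = 1 - S/L`
#' (0 = straight, 1 = fully convoluted), mean ground speed, radiance
#' statistics along the track, and the colony/grounding-place radiance
#' ratio.
#'
#' Speed is computed over the segment ending at the first on-water rest —
#' the first fix over sea whose incoming segment speed falls below
#' `rest_speed_kmh` — because birds that land on the water stop moving at
#' flight speed; if no rest is detected the whole track is used. Rest
#' detection requires a DEM; without one the whole track is used.
#'
#' @param track a [track()].
#' @param sunset a `sunset_spec` from [apparent_sunset()] or a POSIXct UTC
#'   instant.
#' @param radiance radiance [raster_grid()], or `NULL` to skip radiance
#'   statistics.
#' @param colony `c(lon, lat)` of the natal (or release) colony.
#' @param dem optional elevation [raster_grid()] for on-water rest detection.
#' @param rest_speed_kmh speed threshold of the rest detector, km/h.
#' @return one-row data frame with columns `bird_id`, `group`, `timing_min`,
#'   `duration_min`, `length_m`, `straight_length_m`, `tortuosity`,
#'   `speed_kmh`, `max_radiance`, `mean_radiance`, `colony_grounding_ratio`.
#' @export
summarize_flight <- function(track, sunset, radiance = NULL, colony = NULL,
                             dem = NULL, rest_speed_kmh = 5) {
  stopifnot(inherits(track, "fallout_track"))
  if (inherits(sunset, "sunset_spec")) sunset <- sunset$sunset_utc
  fx <- track$fixes
  n <- nrow(fx)
  seg <- geodesic_distance(cbind(fx$lon[-n], fx$lat[-n]),
                           cbind(fx$lon[-1], fx$lat[-1]))
  L <- sum(seg)
  if (L == 0) stop("zero-length track: tortuosity undefined")
  S <- geodesic_distance(c(fx$lon[1], fx$lat[1]), c(fx$lon[n], fx$lat[n]))
  tortuosity <- 1 - S / L
  ## numerical guard: S can exceed L by ellipsoid rounding on 2-fix tracks
  tortuosity <- min(max(tortuosity, 0), 1)
  timing <- as.numeric(difftime(fx$time[1], sunset, units = "mins"))
  if (timing < 0)
    message("bird ", track$bird_id, " departed ", round(-timing, 1),
            " min before sunset")
  duration <- as.numeric(difftime(fx$time[n], fx$time[1], units = "mins"))
  ## on-water rest: first sea fix reached at below rest speed
  end <- n
  if (!is.null(dem)) {
    dt_s <- as.numeric(diff(fx$time), units = "secs")
    seg_speed <- seg / dt_s * 3.6
    idx <- cell_index(dem, fx$lon, fx$lat)
    on_sea <- !is.na(idx$row) & sea_mask(dem)[cbind(idx$row, idx$col)]
    on_sea[is.na(idx$row)] <- TRUE                    # beyond the grid = open sea
    rest <- which(on_sea[-1] & seg_speed < rest_speed_kmh)
    if (length(rest)) end <- rest[1] + 1L
  }
  t_end <- as.numeric(difftime(fx$time[end], fx$time[1], units = "hours"))
  speed <- if (t_end > 0) sum(seg[seq_len(end - 1L)]) / 1000 / t_end else 0
  max_rad <- mean_rad <- ratio <- NA_real_
  if (!is.null(radiance)) {
    exp <- sample_track(radiance, track)
    max_rad <- exp$max_radiance; mean_rad <- exp$mean_radiance
    if (!is.null(colony)) {
      r_col <- sample_point(radiance, colony[1], colony[2])
      ## the final fix can sit beyond the raster (bird escaped to open sea)
      r_gnd <- tryCatch(sample_point(radiance, fx$lon[n], fx$lat[n]),
                        error = function(e) NA_real_)
      ratio <- if (!is.na(r_gnd) && r_gnd > 0) r_col / r_gnd else NA_real_
    }
  }
  data.frame(bird_id = track$bird_id, group = track$group,
             timing_min = timing, duration_min = duration, length_m = L,
             straight_length_m = S, tortuosity = tortuosity,
             speed_kmh = speed, max_radiance = max_rad,
             mean_radiance = mean_rad, colony_grounding_ratio = ratio)
}

#' Summarise a simulated cohort
#'
#' Applies [summarize_flight()] to every track of a [simulate_cohort()]
#' result, using each bird's own colony and departure night sunset.
#'
#' @param cohort result of [simulate_cohort()].
#' @param colonies data frame from [place_colonies()].
#' @param sunset POSIXct UTC sunset or `sunset_spec`.
#' @param radiance radiance [raster_grid()].
#' @param dem optional elevation [raster_grid()].
#' @return data frame, one row per flight, with `colony_id` and `outcome`
#'   joined on.
#' @export
summarize_cohort <- function(cohort, colonies, sunset, radiance, dem = NULL) {
  rows <- lapply(seq_along(cohort$tracks), function(i) {
    b <- cohort$birds[i, ]
    cl <- colonies[colonies$colony_id == b$colony_id, ]
    s <- summarize_flight(cohort$tracks[[i]], sunset, radiance,
                          colony = c(cl$lon, cl$lat), dem = dem)
    s$colony_id <- b$colony_id
    s$outcome <- b$outcome
    s
  })
  do.call(rbind, rows)
}
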