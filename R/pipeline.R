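#' Read a pipeline run configuration
#'
#' Plain-text `key = value` format with `[section]` headers. Unknown keys
#' are kept verbatim; values that parse as numbers are converted. Exactly
#' one of two sections must be present: `[scenario]`, configuring the
#' synthetic nightscape, or `[inputs]`, pointing at real data files
#' (`tracks`, `radiance`, `dem`, `burrows`).
#'
#' @param path config file path.
#' @return nested named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  cfg <- list(); section <- "global"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(cfg[[section]])) cfg[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
      num <- suppressWarnings(as.numeric(val))
      cfg[[section]][[key]] <- if (!is.na(num)) num else val
    } else stop("malformed config line: ", ln)
  }
  has_scn <- !is.null(cfg$scenario); has_inp <- !is.null(cfg$inputs)
  if (has_scn == has_inp)
    stop("config must contain exactly one of [scenario] or [inputs]")
  structure(cfg, class = "run_config")
}

cfg_get <- function(cfg, section, key, default) {
  v <- cfg[[section]][[key]]
  if (is.null(v)) default else v
}

#' Run the full pipeline
#'
#' Executes every stage in order — data acquisition (synthetic nightscape
#' generation or file loading), colony exposure extraction, flight metrics,
#' randomisation and correlation tests, grounding-rate model ranking, and
#' population back-calculation — writing plain CSV/ASCII-grid outputs plus
#' a JSON manifest (config echo, seed, file checksums), so each stage is
#' independently re-runnable and identical config + seed reproduces
#' byte-identical outputs.
#'
#' With real inputs, each flight is assigned to the colony whose centroid
#' is nearest its first fix, and sunset is computed per flight at its own
#' date and departure location.
#'
#' @param config a `run_config` (from [read_run_config()]) or a path to one.
#' @param out_dir output directory, created if missing; overrides the
#'   config's `output_dir`.
#' @return invisibly, the manifest list.
#' @export
run_all <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- out_dir %||% cfg_get(config, "global", "output_dir", "fallout_run")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg_get(config, "global", "seed", 1))
  stage <- function(name, expr) {
    message("[", name, "] running")
    tryCatch(expr, error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
  }
  buffer_m <- cfg_get(config, "global", "buffer_radius_km", 3) * 1000

  if (!is.null(config$scenario)) {
    acq <- stage("simulate", acquire_synthetic(config, seed, out_dir))
  } else {
    acq <- stage("load", acquire_inputs(config, buffer_m))
  }

  utils::write.csv(acq$colonies_cov[, setdiff(names(acq$colonies_cov),
                                              c("p_true", "members"))],
                   file.path(out_dir, "colonies.csv"),
                   row.names = FALSE, quote = FALSE)

  summaries <- stage("metrics", do.call(rbind, lapply(acq$flights, function(fl)
    cbind(summarize_flight(fl$track, fl$sunset, acq$radiance,
                           colony = fl$colony, dem = acq$dem),
          colony_id = fl$colony_id, outcome = fl$outcome))))
  utils::write.csv(summaries, file.path(out_dir, "summaries.csv"),
                   row.names = FALSE, quote = FALSE)

  tests <- stage("tests", {
    n_it <- cfg_get(config, "global", "n_iterations", 9999)
    ex_lim <- cfg_get(config, "global", "exhaustive_limit", 200000)
    out <- NULL
    if (length(unique(summaries$group)) == 2L) {
      out <- do.call(rbind, lapply(c("tortuosity", "speed_kmh"), function(v) {
        r <- randomisation_test(
          summaries[[v]][summaries$group == "first_flight"],
          summaries[[v]][summaries$group == "second_flight"],
          exhaustive_limit = ex_lim, n_iterations = n_it, seed = seed + 5L)
        data.frame(test = paste0("randomisation_", v), statistic = r$statistic,
                   p_value = r$p_value, method = r$method)
      }))
    }
    grounded <- summaries[summaries$outcome == "grounded" &
                            is.finite(summaries$colony_grounding_ratio), ]
    if (nrow(grounded) >= 5 && stats::sd(grounded$straight_length_m) > 0) {
      ## radiance differential grounding - colony, from the stored ratio
      diffs <- 1 / grounded$colony_grounding_ratio
      r <- spearman_mc_test(grounded$straight_length_m, diffs,
                            tail = "greater", n_iterations = n_it,
                            seed = seed + 6L)
      out <- rbind(out, data.frame(
        test = "spearman_straight_length_vs_radiance",
        statistic = r$rho, p_value = r$p_value, method = "monte_carlo"))
    }
    out
  })
  utils::write.csv(tests, file.path(out_dir, "tests.csv"),
                   row.names = FALSE, quote = FALSE)

  model_table <- stage("glm", {
    fits <- lapply(c("distance_to_sea_m", "elevation_m", "radiance_mean_3km",
                     "radiance_max_3km", "radiance_at_colony", "none"),
                   function(v) tryCatch(
                     fit_binomial_logit(acq$colonies_cov, v),
                     error = function(e) {
                       message("dropping candidate model [", v, "]: ",
                               conditionMessage(e))
                       NULL
                     }))
    rank_models(Filter(Negate(is.null), fits))
  })
  utils::write.csv(model_table, file.path(out_dir, "model_table.csv"),
                   row.names = FALSE, quote = FALSE)

  pop <- stage("popsize", {
    rate <- sum(acq$colonies_cov$n_recovered) / sum(acq$colonies_cov$n_banded)
    lapply(c(min = cfg_get(config, "global", "rescued_min", 863),
             max = cfg_get(config, "global", "rescued_max", 1751)),
           function(m) estimate_population(
             m, rate, cfg_get(config, "global", "breeding_success", 0.75)))
  })
  utils::write.csv(data.frame(
    scenario = names(pop),
    rescued = vapply(pop, `[[`, numeric(1), "rescued"),
    grounding_rate = vapply(pop, `[[`, numeric(1), "grounding_rate"),
    pairs = vapply(pop, `[[`, numeric(1), "pairs")),
    file.path(out_dir, "popsize.csv"), row.names = FALSE, quote = FALSE)

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("fallout")),
    seed = seed,
    config = unclass(config),
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

## Synthetic acquisition: generate island, colonies, two flight cohorts and
## colony outcomes; write the raw layers alongside the analysis outputs.
acquire_synthetic <- function(config, seed, out_dir) {
  ncfg <- nightscape_config(
    island_radius_m = cfg_get(config, "scenario", "island_radius_m", 12000),
    peak_elevation_m = cfg_get(config, "scenario", "peak_elevation_m", 3718),
    dem_cell_m = cfg_get(config, "scenario", "dem_cell_m", 25),
    n_lights = cfg_get(config, "scenario", "n_lights", 60),
    seed = seed)
  island <- make_island(ncfg)
  write_raster(island$dem, file.path(out_dir, "dem.asc"))
  write_raster(island$radiance, file.path(out_dir, "radiance.asc"))
  colonies <- place_colonies(
    island$dem, n_colonies = cfg_get(config, "scenario", "n_colonies", 17),
    seed = seed + 1L)
  sunset <- apparent_sunset(cfg_get(config, "scenario", "date", "2013-10-25"),
                            ncfg$centre_lon, ncfg$centre_lat)
  n_birds <- cfg_get(config, "scenario", "n_birds", 60)
  coh1 <- simulate_cohort(
    ceiling(n_birds / 2), colonies, island$dem, island$radiance,
    flight_config(seed = seed, persistence =
                    cfg_get(config, "scenario", "persistence_first", 0.9)),
    sunset, seed = seed + 2L, group = "first_flight")
  coh2 <- simulate_cohort(
    floor(n_birds / 2), colonies, island$dem, island$radiance,
    flight_config(seed = seed, persistence =
                    cfg_get(config, "scenario", "persistence_second", 0.6)),
    sunset, seed = seed + 3L, group = "second_flight")
  tracks <- c(coh1$tracks, coh2$tracks)
  birds <- rbind(coh1$birds, coh2$birds)
  write_tracks(tracks, file.path(out_dir, "tracks.csv"))
  rescues <- birds[birds$outcome == "grounded", ]
  utils::write.csv(data.frame(
    bird_id = rescues$bird_id, lon = rescues$ground_lon,
    lat = rescues$ground_lat,
    found_time = format(rescues$departure_time + 3600 * 6,
                        "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")),
    file.path(out_dir, "rescues.csv"), row.names = FALSE, quote = FALSE)
  cov <- colony_covariates(
    data.frame(colony_id = colonies$colony_id, centre_lon = colonies$lon,
               centre_lat = colonies$lat),
    island$dem, island$radiance,
    buffer_radius_m = cfg_get(config, "global", "buffer_radius_km", 3) * 1000)
  colonies_cov <- simulate_colony_outcomes(
    cov, grounding_config(),
    n_banded = cfg_get(config, "scenario", "n_banded", 16), seed = seed + 4L)
  flights <- lapply(seq_along(tracks), function(i) {
    cl <- colonies[colonies$colony_id == birds$colony_id[i], ]
    list(track = tracks[[i]], sunset = sunset, colony = c(cl$lon, cl$lat),
         colony_id = birds$colony_id[i], outcome = birds$outcome[i])
  })
  list(dem = island$dem, radiance = island$radiance, colonies = colonies,
       colonies_cov = colonies_cov, flights = flights)
}

## Real-data acquisition: load rasters, tracks and the burrow table;
## cluster burrows into colonies and assign each flight to the nearest one.
acquire_inputs <- function(config, buffer_m) {
  need <- c("tracks", "radiance", "dem", "burrows")
  miss <- need[!need %in% names(config$inputs)]
  if (length(miss))
    stop("[inputs] config is missing: ", paste(miss, collapse = ", "))
  dem <- read_raster(config$inputs$dem, kind = "elevation_m")
  radiance <- read_raster(config$inputs$radiance)
  tracks <- read_tracks(config$inputs$tracks)
  burrows <- read_burrow_table(config$inputs$burrows)
  cl <- cluster_burrows(burrows,
                        threshold_m = cfg_get(config, "global",
                                              "colony_threshold_m", 1000))
  colonies <- data.frame(colony_id = cl$colony_id, lon = cl$centre_lon,
                         lat = cl$centre_lat, n_banded = cl$n_banded,
                         n_recovered = cl$n_recovered)
  centres <- cbind(colonies$lon, colonies$lat)
  flights <- lapply(tracks, function(tr) {
    first <- c(tr$fixes$lon[1], tr$fixes$lat[1])
    k <- which.min(geosphere::distGeo(centres, first))
    sunset <- apparent_sunset(as.Date(tr$fixes$time[1]), first[1], first[2])
    ## a flight whose last fix lies over land is treated as grounded
    last_idx <- cell_index(dem, tr$fixes$lon[nrow(tr$fixes)],
                           tr$fixes$lat[nrow(tr$fixes)])
    outcome <- if (!is.na(last_idx$row) &&
                   !sea_mask(dem)[last_idx$row, last_idx$col])
      "grounded" else "reached_sea"
    list(track = tr, sunset = sunset, colony = centres[k, ],
         colony_id = colonies$colony_id[k], outcome = outcome)
  })
  cov <- colony_covariates(
    data.frame(colony_id = colonies$colony_id, centre_lon = colonies$lon,
               centre_lat = colonies$lat), dem, radiance,
    buffer_radius_m = buffer_m)
  cov$n_banded <- colonies$n_banded
  cov$n_recovered <- colonies$n_recovered
  list(dem = dem, radiance = radiance, colonies = colonies,
       colonies_cov = cov, flights = flights)
}
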