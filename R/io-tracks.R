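#' Construct a GPS track
#'
#' A track is the ordered sequence of GPS fixes for one bird's flight, from
#' burrow departure to grounding or landing. Fixes are sorted by time and
#' duplicate timestamps collapsed to their first occurrence.
#'
#' @param bird_id character identifier (band or logger id).
#' @param fixes data frame with columns `time` (POSIXct, UTC), `lon`, `lat`
#'   (degrees WGS84) and optionally `altitude` (m, device-reported; may be
#'   `NA`).
#' @param group `"first_flight"` (natural maiden flight from the nest burrow)
#'   or `"second_flight"` (rescued bird re-released and tracked again).
#' @param nominal_interval_s programmed fix interval in seconds (10, 15 or 30
#'   in typical deployments).
#' @return object of class `fallout_track`.
#' @export
track <- function(bird_id, fixes, group = c("first_flight", "second_flight"),
                  nominal_interval_s = 30) {
  group <- match.arg(group)
  stopifnot(is.data.frame(fixes), all(c("time", "lon", "lat") %in% names(fixes)))
  if (!inherits(fixes$time, "POSIXct"))
    stop("fixes$time must be POSIXct (UTC)")
  attr(fixes$time, "tzone") <- "UTC"
  if (is.null(fixes$altitude)) fixes$altitude <- NA_real_
  if (any(fixes$lat < -90 | fixes$lat > 90, na.rm = TRUE))
    stop("latitude out of [-90, 90] for bird ", bird_id)
  if (any(fixes$lon < -180 | fixes$lon > 180, na.rm = TRUE))
    stop("longitude out of [-180, 180] for bird ", bird_id)
  fixes <- fixes[order(fixes$time), c("time", "lon", "lat", "altitude")]
  fixes <- fixes[!duplicated(fixes$time), , drop = FALSE]
  rownames(fixes) <- NULL
  if (nrow(fixes) < 2L)
    stop("track for bird ", bird_id, " has fewer than 2 distinct fixes")
  structure(list(bird_id = as.character(bird_id), group = group,
                 nominal_interval_s = nominal_interval_s, fixes = fixes),
            class = "fallout_track")
}

#' @export
print.fallout_track <- function(x, ...) {
  cat(sprintf("<fallout_track %s (%s): %d fixes, %s .. %s UTC>\n",
              x$bird_id, x$group, nrow(x$fixes),
              format(x$fixes$time[1]), format(x$fixes$time[nrow(x$fixes)])))
  invisible(x)
}

parse_utc <- function(x) {
  t <- as.POSIXct(x, tz = "UTC",
                  tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                                 "%Y-%m-%d %H:%M:%OS"))
  t
}

#' Read GPS tracks from file
#'
#' Supports GPX 1.1 (one track per `<trk>` element, `bird_id` from `<name>`)
#' and a fixed CSV dialect with header `bird_id,time,lon,lat,altitude`
#' (optionally a `group` column), ISO-8601 UTC times, decimal point, UTF-8.
#' Fixes are sorted by time per bird and duplicate timestamps dropped; birds
#' with fewer than 2 usable fixes are excluded with a warning.
#'
#' @param path file path.
#' @param dialect `"gpx"` or `"csv"`; default guesses from the extension.
#' @param group group assigned to tracks that do not carry one.
#' @param nominal_interval_s programmed fix interval, stored on each track.
#' @return list of [track()] objects, one per bird.
#' @export
read_tracks <- function(path, dialect = c("auto", "gpx", "csv"),
                        group = "first_flight", nominal_interval_s = 30) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("track file not found: ", path)
  if (dialect == "auto")
    dialect <- if (grepl("\\.gpx$", path, ignore.case = TRUE)) "gpx" else "csv"
  if (dialect == "gpx") read_tracks_gpx(path, group, nominal_interval_s)
  else read_tracks_csv(path, group, nominal_interval_s)
}

read_tracks_csv <- function(path, group, nominal_interval_s) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("bird_id", "time", "lon", "lat", "altitude")
  if (!all(need %in% names(df)))
    stop("CSV track file must have header bird_id,time,lon,lat,altitude")
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & nzchar(df[[col]]) & col != "altitude")
    if (length(bad))
      stop("malformed ", col, " at line ", bad[1] + 1L, " of ", path)
    v
  }
  tm <- parse_utc(df$time)
  if (anyNA(tm))
    stop("malformed time at line ", which(is.na(tm))[1] + 1L, " of ", path)
  df2 <- data.frame(bird_id = df$bird_id, time = tm, lon = num("lon"),
                    lat = num("lat"), altitude = suppressWarnings(as.numeric(df$altitude)))
  grp <- if ("group" %in% names(df)) df$group else rep(group, nrow(df))
  out <- list()
  for (id in unique(df2$bird_id)) {
    sub <- df2[df2$bird_id == id, ]
    if (nrow(sub[!duplicated(sub$time), ]) < 2L) {
      warning("excluding track ", id, ": fewer than 2 distinct fixes")
      next
    }
    out[[id]] <- track(id, sub[, c("time", "lon", "lat", "altitude")],
                       group = grp[df2$bird_id == id][1],
                       nominal_interval_s = nominal_interval_s)
  }
  unname(out)
}

read_tracks_gpx <- function(path, group, nominal_interval_s) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  trks <- xml2::xml_find_all(doc, ".//g:trk", ns)
  if (length(trks) == 0L) trks <- xml2::xml_find_all(doc, ".//trk")
  out <- list()
  for (k in seq_along(trks)) {
    trk <- trks[[k]]
    nm <- xml2::xml_text(xml2::xml_find_first(trk, "./g:name", ns))
    if (is.na(nm) || !nzchar(nm)) nm <- sprintf("track_%02d", k)
    pts <- xml2::xml_find_all(trk, ".//g:trkpt", ns)
    if (length(pts) == 0L) pts <- xml2::xml_find_all(trk, ".//trkpt")
    if (length(pts) < 2L) {
      warning("excluding GPX track ", nm, ": fewer than 2 fixes")
      next
    }
    ele <- suppressWarnings(as.numeric(
      xml2::xml_text(xml2::xml_find_first(pts, "./g:ele", ns))))
    tim <- parse_utc(xml2::xml_text(xml2::xml_find_first(pts, "./g:time", ns)))
    fixes <- data.frame(
      time = tim,
      lon = as.numeric(xml2::xml_attr(pts, "lon")),
      lat = as.numeric(xml2::xml_attr(pts, "lat")),
      altitude = ele)
    out[[nm]] <- track(nm, fixes, group = group,
                       nominal_interval_s = nominal_interval_s)
  }
  unname(out)
}

#' Write tracks to CSV or GPX
#'
#' @param tracks list of [track()] objects.
#' @param path output path; format from `dialect` or the extension.
#' @param dialect `"auto"`, `"gpx"` or `"csv"`.
#' @export
write_tracks <- function(tracks, path, dialect = c("auto", "gpx", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.gpx$", path, ignore.case = TRUE)) "gpx" else "csv"
  if (dialect == "csv") {
    rows <- do.call(rbind, lapply(tracks, function(tr)
      data.frame(bird_id = tr$bird_id,
                 time = format(tr$fixes$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                 lon = tr$fixes$lon, lat = tr$fixes$lat,
                 altitude = tr$fixes$altitude, group = tr$group)))
    utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  } else {
    doc <- xml2::xml_new_root("gpx", version = "1.1", creator = "fallout",
                              xmlns = "http://www.topografix.com/GPX/1/1")
    for (tr in tracks) {
      trk <- xml2::xml_add_child(doc, "trk")
      xml2::xml_add_child(trk, "name", tr$bird_id)
      seg <- xml2::xml_add_child(trk, "trkseg")
      for (i in seq_len(nrow(tr$fixes))) {
        pt <- xml2::xml_add_child(seg, "trkpt",
                                  lat = sprintf("%.8f", tr$fixes$lat[i]),
                                  lon = sprintf("%.8f", tr$fixes$lon[i]))
        if (!is.na(tr$fixes$altitude[i]))
          xml2::xml_add_child(pt, "ele", sprintf("%.2f", tr$fixes$altitude[i]))
        xml2::xml_add_child(pt, "time",
                            format(tr$fixes$time[i], "%Y-%m-%dT%H:%M:%SZ",
                                   tz = "UTC"))
      }
    }
    xml2::write_xml(doc, path)
  }
  invisible(NULL)
}
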