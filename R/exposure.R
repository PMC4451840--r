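#' Sample a raster at a point
#'
#' Value of the cell containing the point (no interpolation), mirroring the
#' "pixel value intersected with the colony centre" measure of light-pollution
#' exposure. Cell membership uses the half-open convention documented in
#' [raster_grid()]: a point on a shared cell edge belongs to the cell to its
#' east/south.
#'
#' @param grid a [raster_grid()].
#' @param lon,lat point(s) in degrees; vectors are sampled element-wise.
#' @return cell value(s); `NA` for missing (nodata) cells.
#' @export
sample_point <- function(grid, lon, lat) {
  idx <- cell_index(grid, lon, lat)
  if (anyNA(idx$row))
    stop("point outside raster extent: (",
         lon[which(is.na(idx$row))[1]], ", ", lat[which(is.na(idx$row))[1]], ")")
  grid$values[cbind(idx$row, idx$col)]
}

## 0-based grid cells traversed by the segment (u1,v1) -> (u2,v2) in
## continuous grid coordinates, by Amanatides-Woo traversal. Returns a
## two-column matrix (cu, cv).
traverse_cells_uv <- function(u1, v1, u2, v2) {
  cu <- floor(u1); cv <- floor(v1)
  eu <- floor(u2); ev <- floor(v2)
  cells <- matrix(c(cu, cv), ncol = 2)
  du <- u2 - u1; dv <- v2 - v1
  step_u <- sign(du); step_v <- sign(dv)
  t_du <- if (du != 0) abs(1 / du) else Inf
  t_dv <- if (dv != 0) abs(1 / dv) else Inf
  t_mu <- if (du > 0) (cu + 1 - u1) / du else if (du < 0) (cu - u1) / du else Inf
  t_mv <- if (dv > 0) (cv + 1 - v1) / dv else if (dv < 0) (cv - v1) / dv else Inf
  guard <- 4L * (abs(eu - cu) + abs(ev - cv) + 2L)
  it <- 0L
  while ((cu != eu || cv != ev) && it < guard) {
    if (t_mu < t_mv) { cu <- cu + step_u; t_mu <- t_mu + t_du }
    else             { cv <- cv + step_v; t_mv <- t_mv + t_dv }
    cells <- rbind(cells, c(cu, cv))
    it <- it + 1L
  }
  cells
}

#' Radiance exposure along a flight track
#'
#' Collects the set of distinct raster cells crossed by the track polyline
#' (exact grid-line traversal between consecutive fixes, plus both endpoints)
#' and returns the mean and maximum value over that set; each traversed cell
#' counts once regardless of dwell length, and missing cells are excluded.
#'
#' @param grid a [raster_grid()].
#' @param track a [track()] object, or a data frame with `lon`/`lat` columns.
#' @param weighted if `TRUE`, the mean is weighted by the path length spent
#'   in each cell instead of counting each traversed cell once (the
#'   unweighted version is canonical).
#' @return list with `mean_radiance`, `max_radiance` and `n_cells`.
#' @export
sample_track <- function(grid, track, weighted = FALSE) {
  fx <- if (inherits(track, "fallout_track")) track$fixes else track
  if (nrow(fx) < 2L) stop("track must have at least 2 fixes")
  uv <- grid_uv(grid, fx$lon, fx$lat)
  cells <- NULL; wts <- NULL
  for (i in seq_len(nrow(fx) - 1L)) {
    seg <- traverse_cells_uv(uv$u[i], uv$v[i], uv$u[i + 1L], uv$v[i + 1L])
    if (weighted) {
      len <- geodesic_distance(c(fx$lon[i], fx$lat[i]),
                               c(fx$lon[i + 1L], fx$lat[i + 1L]))
      wts <- c(wts, rep(len / nrow(seg), nrow(seg)))
    }
    cells <- rbind(cells, seg)
  }
  row <- cells[, 2] + 1L; col <- cells[, 1] + 1L
  keep <- row >= 1L & row <= grid$n_rows & col >= 1L & col <= grid$n_cols
  if (!any(keep)) stop("track does not overlap the raster")
  row <- row[keep]; col <- col[keep]
  if (weighted) {
    wts <- wts[keep]
    vals <- grid$values[cbind(row, col)]
    ok <- !is.na(vals)
    if (!any(ok)) stop("no valid raster cells under the track")
    return(list(mean_radiance = sum(vals[ok] * wts[ok]) / sum(wts[ok]),
                max_radiance = max(vals[ok]),
                n_cells = length(unique(paste(row[ok], col[ok])))))
  }
  cell_id <- (row - 1L) * grid$n_cols + col
  uniq <- !duplicated(cell_id)
  vals <- grid$values[cbind(row[uniq], col[uniq])]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) stop("no valid raster cells under the track")
  list(mean_radiance = mean(vals), max_radiance = max(vals),
       n_cells = length(vals))
}

#' Buffer statistics around a point
#'
#' Mean and maximum raster value over all cells whose centre lies within
#' `radius_m` (geodesic) of the point — the "3 km radius around the colony
#' centre" light-pollution summary. The cell containing the point is always
#' included, so a radius smaller than half a cell degenerates to that single
#' cell. Missing cells are excluded.
#'
#' @param grid a [raster_grid()].
#' @param centre `c(lon, lat)` in degrees.
#' @param radius_m buffer radius in metres (> 0).
#' @return named list with `mean`, `max` and `n_cells`.
#' @export
buffer_stats <- function(grid, centre, radius_m) {
  if (radius_m <= 0) stop("radius_m must be > 0")
  lon <- centre[1]; lat <- centre[2]
  ## bounding box with a 10% margin; 1 deg latitude ~ 111 km
  ddeg <- radius_m / 111000 * 1.1
  ddeg_lon <- ddeg / max(cos(lat * pi / 180), 0.1)
  idx <- cell_index(grid, lon, lat)
  if (anyNA(idx$row)) stop("buffer centre outside raster extent")
  r0 <- max(1L, floor((grid$y_origin - (lat + ddeg)) / grid$cell_size) + 1L)
  r1 <- min(grid$n_rows, floor((grid$y_origin - (lat - ddeg)) / grid$cell_size) + 1L)
  c0 <- max(1L, floor((lon - ddeg_lon - grid$x_origin) / grid$cell_size) + 1L)
  c1 <- min(grid$n_cols, floor((lon + ddeg_lon - grid$x_origin) / grid$cell_size) + 1L)
  rows <- rep(r0:r1, times = c1 - c0 + 1L)
  cols <- rep(c0:c1, each = r1 - r0 + 1L)
  ctr <- cell_centre(grid, rows, cols)
  d <- geosphere::distGeo(cbind(ctr$lon, ctr$lat), c(lon, lat))
  inside <- d <= radius_m | (rows == idx$row & cols == idx$col)
  vals <- grid$values[cbind(rows[inside], cols[inside])]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) stop("no valid cells within the buffer")
  list(mean = mean(vals), max = max(vals), n_cells = length(vals))
}

## Sea mask: nodata or elevation <= 0.
sea_mask <- function(dem) is.na(dem$values) | dem$values <= 0

## Row/col of sea cells that touch land (4-neighbourhood) — the coastline.
coast_cells <- function(dem) {
  sea <- sea_mask(dem)
  land <- !sea
  nr <- nrow(sea); nc <- ncol(sea)
  pad <- function(m) {
    out <- matrix(FALSE, nr, nc)
    out
  }
  nb_land <- pad(sea)
  nb_land[-1, ] <- nb_land[-1, ] | land[-nr, ]
  nb_land[-nr, ] <- nb_land[-nr, ] | land[-1, ]
  nb_land[, -1] <- nb_land[, -1] | land[, -nc]
  nb_land[, -nc] <- nb_land[, -nc] | land[, -1]
  which(sea & nb_land, arr.ind = TRUE)
}

#' Distance to the sea
#'
#' Minimum geodesic distance from a point to the centre of any sea cell of
#' the DEM, where sea is defined as nodata or elevation <= 0. Points already
#' over sea return 0 with a warning.
#'
#' @param dem elevation [raster_grid()].
#' @param lon,lat point(s) in degrees; vectors are processed element-wise.
#' @return distance(s) in metres.
#' @export
distance_to_sea <- function(dem, lon, lat) {
  sea <- sea_mask(dem)
  if (!any(sea)) stop("DEM contains no sea cells")
  coast <- coast_cells(dem)
  ## fall back to all sea cells if land/sea never touch (degenerate grids)
  if (nrow(coast) == 0L) coast <- which(sea, arr.ind = TRUE)
  ctr <- cell_centre(dem, coast[, 1], coast[, 2])
  coast_pts <- cbind(ctr$lon, ctr$lat)
  idx <- cell_index(dem, lon, lat)
  out <- numeric(length(lon))
  for (i in seq_along(lon)) {
    if (!is.na(idx$row[i]) && sea[idx$row[i], idx$col[i]]) {
      warning("point (", lon[i], ", ", lat[i], ") is over sea; distance 0")
      out[i] <- 0
    } else {
      out[i] <- min(geosphere::distGeo(coast_pts, c(lon[i], lat[i])))
    }
  }
  out
}

#' Cluster nest burrows into colonies
#'
#' Single-linkage clustering with a distance threshold: two burrows belong to
#' the same colony iff a chain of pairwise links, each no longer than
#' `threshold_m`, connects them. The default 1 km implements the rule that
#' burrows more than 1 km apart belong to different colonies. Note the
#' chaining behaviour: burrows 1.8 km apart still share a colony if a third
#' burrow sits between them.
#'
#' @param burrows data frame from [read_burrow_table()].
#' @param threshold_m linkage threshold in metres.
#' @return data frame with one row per colony: `colony_id`, `centre_lon`,
#'   `centre_lat` (centroid of member burrows), summed `n_banded` and
#'   `n_recovered`, `n_burrows`, and a `members` list-column of burrow ids.
#'   Colonies are ordered south to north so the partition (and its labels)
#'   does not depend on input row order.
#' @export
cluster_burrows <- function(burrows, threshold_m = 1000) {
  validate_burrows(burrows)
  n <- nrow(burrows)
  if (n == 0L) stop("at least one burrow is required")
  pts <- cbind(burrows$lon, burrows$lat)
  comp <- seq_len(n)
  if (n > 1L) {
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      j <- (i + 1L):n
      d[i, j] <- d[j, i] <- geosphere::distGeo(pts[rep(i, length(j)), , drop = FALSE],
                                               pts[j, , drop = FALSE])
    }
    adj <- d <= threshold_m
    ## connected components by label propagation
    repeat {
      new <- apply(adj, 1L, function(a) min(comp[a]))
      if (all(new == comp)) break
      comp <- new
    }
  }
  ids <- unique(comp)
  out <- do.call(rbind, lapply(ids, function(k) {
    m <- comp == k
    data.frame(centre_lon = mean(burrows$lon[m]),
               centre_lat = mean(burrows$lat[m]),
               n_banded = sum(burrows$n_banded[m]),
               n_recovered = sum(burrows$n_recovered[m]),
               n_burrows = sum(m))
  }))
  members <- lapply(ids, function(k) sort(burrows$burrow_id[comp == k]))
  ord <- order(out$centre_lat, out$centre_lon)
  out <- out[ord, , drop = FALSE]
  out$members <- members[ord]
  out <- cbind(colony_id = sprintf("colony_%02d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Attach physical and light-pollution covariates to colonies
#'
#' Computes, for each colony centre: DEM elevation, geodesic distance to the
#' sea, radiance of the containing pixel, and mean/maximum radiance within a
#' buffer (default 3 km) — the candidate explanatory variables of the
#' grounding-rate models.
#'
#' @param colonies data frame from [cluster_burrows()] (or any data frame
#'   with `centre_lon`/`centre_lat`).
#' @param dem elevation [raster_grid()].
#' @param radiance radiance [raster_grid()].
#' @param buffer_radius_m buffer radius in metres.
#' @return `colonies` with columns `elevation_m`, `distance_to_sea_m`,
#'   `radiance_at_colony`, `radiance_mean_3km`, `radiance_max_3km` appended.
#' @export
colony_covariates <- function(colonies, dem, radiance, buffer_radius_m = 3000) {
  colonies$elevation_m <- sample_point(dem, colonies$centre_lon,
                                       colonies$centre_lat)
  colonies$distance_to_sea_m <- distance_to_sea(dem, colonies$centre_lon,
                                                colonies$centre_lat)
  colonies$radiance_at_colony <- sample_point(radiance, colonies$centre_lon,
                                              colonies$centre_lat)
  buf <- lapply(seq_len(nrow(colonies)), function(i)
    buffer_stats(radiance, c(colonies$centre_lon[i], colonies$centre_lat[i]),
                 buffer_radius_m))
  colonies$radiance_mean_3km <- vapply(buf, `[[`, numeric(1), "mean")
  colonies$radiance_max_3km <- vapply(buf, `[[`, numeric(1), "max")
  colonies
}
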