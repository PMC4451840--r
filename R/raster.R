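#' Construct a raster grid
#'
#' A `raster_grid` is a lightweight in-memory georeferenced cell grid used for
#' the nocturnal radiance image (nW/(sr cm^2)) and the digital elevation model
#' (m). Coordinates are WGS84 longitude/latitude in decimal degrees;
#' `cell_size` is the cell edge in degrees. `x_origin`/`y_origin` locate the
#' outer (north-west) corner of cell (1, 1); rows run north to south.
#'
#' Cell membership follows a half-open convention: cell (r, c) covers
#' longitudes `[x0 + (c-1) s, x0 + c s)` and latitudes
#' `(y0 - r s, y0 - (r-1) s]`, so a point on a shared edge belongs to exactly
#' one cell (the one to its east, respectively south).
#'
#' @param values numeric matrix (rows north to south) of cell values; `NA`
#'   marks missing cells.
#' @param x_origin,y_origin longitude/latitude of the north-west corner, in
#'   degrees.
#' @param cell_size cell edge in degrees (> 0).
#' @param nodata sentinel written to file for missing cells.
#' @param kind `"radiance_nW_sr_cm2"` or `"elevation_m"`.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, x_origin, y_origin, cell_size,
                        nodata = -9999,
                        kind = c("radiance_nW_sr_cm2", "elevation_m")) {
  kind <- match.arg(kind)
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  g <- structure(
    list(values = values, x_origin = as.numeric(x_origin),
         y_origin = as.numeric(y_origin), cell_size = as.numeric(cell_size),
         n_rows = nrow(values), n_cols = ncol(values),
         nodata = as.numeric(nodata), kind = kind),
    class = "raster_grid")
  validate_raster_grid(g)
  g
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid [%s]: %d x %d cells, cell %g deg, NW corner (%g, %g)>\n",
              x$kind, x$n_rows, x$n_cols, x$cell_size, x$x_origin, x$y_origin))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  values in [%g, %g], %d missing\n", rng[1], rng[2],
              sum(is.na(x$values))))
  invisible(x)
}

validate_raster_grid <- function(g) {
  stopifnot(inherits(g, "raster_grid"))
  if (g$cell_size <= 0) stop("cell_size must be > 0")
  if (length(g$values) != g$n_rows * g$n_cols)
    stop("values length does not match n_rows x n_cols")
  if (g$kind == "radiance_nW_sr_cm2" && any(g$values < 0, na.rm = TRUE))
    stop("radiance values must be >= 0 where not missing")
  invisible(g)
}

## Continuous grid coordinates: u along columns, v along rows, both with the
## floor() half-open convention (u in [c-1, c) lies in column c).
grid_uv <- function(grid, lon, lat) {
  list(u = (lon - grid$x_origin) / grid$cell_size,
       v = (grid$y_origin - lat) / grid$cell_size)
}

## Row/column of the cell containing each point; NA row/col when outside.
cell_index <- function(grid, lon, lat) {
  uv <- grid_uv(grid, lon, lat)
  col <- floor(uv$u) + 1L
  row <- floor(uv$v) + 1L
  bad <- col < 1L | col > grid$n_cols | row < 1L | row > grid$n_rows
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

## Longitude/latitude of cell centres.
cell_centre <- function(grid, row, col) {
  list(lon = grid$x_origin + (col - 0.5) * grid$cell_size,
       lat = grid$y_origin - (row - 0.5) * grid$cell_size)
}

#' Read a raster from file
#'
#' Reads an ESRI ASCII grid (`.asc`). GeoTIFF and other binary rasters are
#' detected by their magic bytes and rejected with an error naming the format;
#' convert them to ASCII grid before use.
#'
#' @param path file path.
#' @param kind value semantics of the grid; see [raster_grid()].
#' @return a [raster_grid()].
#' @export
read_raster <- function(path, kind = c("radiance_nW_sr_cm2", "elevation_m")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("raster file not found: ", path)
  magic <- readBin(path, "raw", n = 4L)
  if (length(magic) >= 4L &&
      (identical(magic[1:2], as.raw(c(0x49, 0x49))) ||
       identical(magic[1:2], as.raw(c(0x4d, 0x4d)))))
    stop("unsupported raster format: GeoTIFF/TIFF detected; ",
         "convert to ESRI ASCII grid (.asc)")
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1L
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2L || is.na(suppressWarnings(as.numeric(parts[2]))))
      break
    key <- tolower(parts[1])
    if (!key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
                    "yllcenter", "cellsize", "nodata_value"))
      break
    hdr[[key]] <- as.numeric(parts[2]); i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("unsupported raster format: missing ESRI ASCII grid header in ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("ASCII grid body has ", length(vals), " values, expected ", nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  cs <- hdr$cellsize
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - cs / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - cs / 2
  raster_grid(m, x_origin = xll, y_origin = yll + nr * cs, cell_size = cs,
              nodata = nodata, kind = kind)
}

#' Write a raster to an ESRI ASCII grid file
#'
#' Values are written in full double precision (`%.17g`) so that a
#' write/read round trip is bit-exact.
#'
#' @param grid a [raster_grid()].
#' @param path output path (conventionally `.asc`).
#' @export
write_raster <- function(grid, path) {
  validate_raster_grid(grid)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.17g", grid$x_origin),
    sprintf("yllcorner %.17g", grid$y_origin - grid$n_rows * grid$cell_size),
    sprintf("cellsize %.17g", grid$cell_size),
    sprintf("NODATA_value %.17g", grid$nodata)), con)
  m <- grid$values
  m[is.na(m)] <- grid$nodata
  writeLines(apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " ")),
             con)
  invisible(NULL)
}
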