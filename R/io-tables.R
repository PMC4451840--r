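#' Read a burrow banding table
#'
#' CSV with header `burrow_id,lon,lat,n_banded,n_recovered`: one row per nest
#' burrow with the number of fledglings banded there and the number later
#' recovered grounded in rescue campaigns.
#'
#' @param path CSV file path.
#' @return data frame with the columns above, validated
#'   (`0 <= n_recovered <= n_banded`, coordinates in range).
#' @export
read_burrow_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("burrow_id", "lon", "lat", "n_banded", "n_recovered")
  if (!all(need %in% names(df)))
    stop("burrow table must have header burrow_id,lon,lat,n_banded,n_recovered")
  df$burrow_id <- as.character(df$burrow_id)
  validate_burrows(df)
  df[, need]
}

validate_burrows <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$n_banded < 0) || any(df$n_recovered < 0))
    stop("burrow counts must be non-negative")
  bad <- df$n_recovered > df$n_banded
  if (any(bad))
    stop("n_recovered > n_banded for burrow ", df$burrow_id[which(bad)[1]])
  if (any(abs(df$lat) > 90) || any(abs(df$lon) > 180))
    stop("burrow coordinates out of range")
  invisible(df)
}

#' Read a rescue table
#'
#' CSV with header `bird_id,lon,lat,found_time`: where and when each grounded
#' bird was found. Times are ISO-8601 UTC.
#'
#' @param path CSV file path.
#' @return data frame with `bird_id`, `lon`, `lat`, `found_time` (POSIXct UTC).
#' @export
read_rescue_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("bird_id", "lon", "lat", "found_time")
  if (!all(need %in% names(df)))
    stop("rescue table must have header bird_id,lon,lat,found_time")
  df$bird_id <- as.character(df$bird_id)
  df$found_time <- parse_utc(df$found_time)
  if (nrow(df) && (anyNA(df$found_time)))
    stop("malformed found_time in rescue table")
  if (nrow(df) && (any(abs(df$lat) > 90) || any(abs(df$lon) > 180)))
    stop("rescue coordinates out of range")
  df[, need]
}
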