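#' Read a GPS fix table
#'
#' Schema-validated CSV reader: requires columns seal_id, timestamp, lon,
#' lat, n_satellites; timestamps must parse as ISO-8601 UTC; coordinates must
#' be in range. Violations are rejected with the offending row number.
#'
#' @param path CSV file path.
#' @return data.frame of fixes with POSIXct timestamps.
#' @export
read_fixes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("seal_id", "timestamp", "lon", "lat", "n_satellites")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  ts <- parse_utc(df$timestamp)
  if (anyNA(ts))
    stop(path, ": unparseable timestamp at row ", which(is.na(ts))[1])
  bad <- which(is.na(df$lat) | abs(df$lat) > 90)
  if (length(bad)) stop(path, ": latitude out of range at row ", bad[1])
  bad <- which(is.na(df$lon) | abs(df$lon) > 180)
  if (length(bad)) stop(path, ": longitude out of range at row ", bad[1])
  df$timestamp <- ts
  df
}

#' Read a dive table
#'
#' Requires seal_id, start_time, end_time, max_depth_m, duration_s; checks
#' ISO-8601 UTC timestamps, end after start, depth above the 1.5 m dive
#' floor, and duration consistent with the times to within 1 s. Extra
#' columns (lon, lat, annotations) pass through, with lat/lon range-checked
#' when present.
#'
#' @param path CSV file path.
#' @return data.frame of dives with POSIXct times.
#' @export
read_dives <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("seal_id", "start_time", "end_time", "max_depth_m", "duration_s")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("start_time", "end_time")) {
    ts <- parse_utc(df[[col]])
    if (anyNA(ts))
      stop(path, ": unparseable ", col, " at row ", which(is.na(ts))[1])
    df[[col]] <- ts
  }
  bad <- which(as.numeric(df$end_time) <= as.numeric(df$start_time))
  if (length(bad)) stop(path, ": end_time not after start_time at row ", bad[1])
  bad <- which(is.na(df$max_depth_m) | df$max_depth_m <= 1.5)
  if (length(bad))
    stop(path, ": max_depth_m missing or below the 1.5 m dive floor at row ",
         bad[1])
  span <- as.numeric(df$end_time) - as.numeric(df$start_time)
  bad <- which(abs(span - df$duration_s) > 1)
  if (length(bad))
    stop(path, ": duration_s inconsistent with start/end at row ", bad[1])
  if ("lat" %in% names(df)) {
    bad <- which(!is.na(df$lat) & abs(df$lat) > 90)
    if (length(bad)) stop(path, ": latitude out of range at row ", bad[1])
  }
  if ("lon" %in% names(df)) {
    bad <- which(!is.na(df$lon) & abs(df$lon) > 180)
    if (length(bad)) stop(path, ": longitude out of range at row ", bad[1])
  }
  df
}

write_dives_csv <- function(dives, path) {
  out <- dives
  for (col in c("start_time", "end_time"))
    if (col %in% names(out)) out[[col]] <- format_utc(out[[col]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
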