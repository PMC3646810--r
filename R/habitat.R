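#' Pool detailed sediment labels into broad habitat classes
#'
#' Collapses EUNIS-style substrate labels to the three broad classes used in
#' the analysis -- fine (mud/sand), coarse (gravel/mixed ground), rock
#' (rock/till) -- with everything else, including missing values, mapped to
#' "unclassified". Matching is case-insensitive on substrings, so
#' "Sandy mud", "gravelly sand" and "MIXED GROUND" all resolve.
#'
#' @param label character vector of sediment labels.
#' @return character vector over fine/coarse/rock/unclassified; total (every
#'   input maps to exactly one class).
#' @export
pool_sediment <- function(label) {
  x <- tolower(trimws(as.character(label)))
  out <- rep("unclassified", length(x))
  out[grepl("rock|till", x)] <- "rock"
  out[grepl("gravel|mixed", x)] <- "coarse"
  out[grepl("mud|sand", x)] <- "fine"
  out[is.na(label)] <- "unclassified"
  out
}

#' Annotate located dives with habitat and diel period
#'
#' Adds to each located dive the charted water depth (`bathy_depth_m`,
#' positive-down metres), the pooled sediment class at the interpolated dive
#' position, and whether the dive started in local day or night. Missing or
#' out-of-extent bathymetry leaves `bathy_depth_m` as `NA` (counted in
#' attribute `n_missing_bathy`); missing sediment becomes "unclassified".
#'
#' @param dives located dives ([interpolate_dive_locations] output).
#' @param depth bathymetry [habitat_raster], positive-down metres.
#' @param sediment sediment-code [habitat_raster] (codes 0:3), or `NULL` to
#'   mark all dives unclassified.
#' @return dives with added `bathy_depth_m`, `sediment`, `diel` columns and
#'   attribute `n_missing_bathy`.
#' @export
annotate_dives <- function(dives, depth, sediment = NULL) {
  req <- c("seal_id", "start_time", "lon", "lat")
  miss <- setdiff(req, names(dives))
  if (length(miss)) stop("dives missing column(s): ", paste(miss, collapse = ", "))
  bd <- extract_at(depth, dives$lon, dives$lat)
  if (!is.null(sediment)) {
    if (!same_geometry(depth, sediment))
      stop("depth and sediment rasters must share geometry")
    sed <- sediment_from_code(extract_at(sediment, dives$lon, dives$lat))
  } else {
    sed <- rep("unclassified", nrow(dives))
  }
  dives$bathy_depth_m <- as.numeric(bd)
  dives$sediment <- sed
  dives$diel <- if (nrow(dives)) {
    is_daytime(dives$start_time, dives$lon, dives$lat)
  } else character(0)
  attr(dives, "n_missing_bathy") <- sum(is.na(bd))
  dives
}
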