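#' Regular lon/lat habitat raster
#'
#' Lightweight container for a regular geographic grid carrying either charted
#' water depth (metres, positive down) or an integer sediment code
#' (0 unclassified, 1 fine, 2 coarse, 3 rock). Values are stored as a matrix
#' whose first row is the *northernmost* row, matching the row order of an
#' ESRI ASCII grid file.
#'
#' @param values numeric matrix, row 1 = north.
#' @param xll,yll longitude/latitude of the lower-left corner of the grid
#'   (degrees).
#' @param cellsize cell edge length in decimal degrees (square cells).
#' @param nodata_value sentinel written to file for missing cells; cells equal
#'   to it are stored as `NA` internally.
#' @return an object of class `habitat_raster`.
#' @export
habitat_raster <- function(values, xll, yll, cellsize, nodata_value = -9999) {
  if (!is.matrix(values) || nrow(values) < 1 || ncol(values) < 1)
    stop("values must be a non-empty matrix")
  if (!is.numeric(cellsize) || length(cellsize) != 1 || cellsize <= 0)
    stop("cellsize must be a single positive number")
  values[!is.na(values) & values == nodata_value] <- NA_real_
  structure(
    list(ncols = ncol(values), nrows = nrow(values),
         xll = as.numeric(xll), yll = as.numeric(yll),
         cellsize = as.numeric(cellsize),
         nodata_value = as.numeric(nodata_value),
         values = values),
    class = "habitat_raster")
}

#' @export
print.habitat_raster <- function(x, ...) {
  cat(sprintf("habitat_raster: %d x %d cells, cellsize %g deg\n",
              x$nrows, x$ncols, x$cellsize))
  cat(sprintf("  extent: lon [%g, %g], lat [%g, %g]\n",
              x$xll, x$xll + x$ncols * x$cellsize,
              x$yll, x$yll + x$nrows * x$cellsize))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  values: [%g, %g], %d NA cells\n",
              rng[1], rng[2], sum(is.na(x$values))))
  invisible(x)
}

raster_extent <- function(r) {
  c(xmin = r$xll, xmax = r$xll + r$ncols * r$cellsize,
    ymin = r$yll, ymax = r$yll + r$nrows * r$cellsize)
}

same_geometry <- function(a, b) {
  isTRUE(all.equal(
    c(a$ncols, a$nrows, a$xll, a$yll, a$cellsize),
    c(b$ncols, b$nrows, b$xll, b$yll, b$cellsize)))
}

#' Extract raster values at points
#'
#' Returns the value of the cell *containing* each point. Cells are half-open
#' rectangles `[x, x + cellsize) x [y, y + cellsize)`, so a point lying on a
#' shared edge belongs to the cell on the higher-index side and never to two
#' cells. Points outside the grid extent and nodata cells yield `NA`; the
#' number of out-of-extent points is attached as attribute `n_outside`.
#'
#' @param raster a [habitat_raster].
#' @param lon,lat numeric vectors of equal length, degrees.
#' @return numeric vector of cell values (`NA` = missing), with attribute
#'   `n_outside`.
#' @export
extract_at <- function(raster, lon, lat) {
  stopifnot(inherits(raster, "habitat_raster"), length(lon) == length(lat))
  col <- floor((lon - raster$xll) / raster$cellsize) + 1
  row_s <- floor((lat - raster$yll) / raster$cellsize) + 1  # 1 = south row
  inside <- !is.na(col) & !is.na(row_s) &
    col >= 1 & col <= raster$ncols & row_s >= 1 & row_s <= raster$nrows
  out <- rep(NA_real_, length(lon))
  if (any(inside)) {
    row_n <- raster$nrows - row_s[inside] + 1  # matrix row (1 = north)
    out[inside] <- raster$values[cbind(row_n, col[inside])]
  }
  attr(out, "n_outside") <- sum(!inside)
  out
}

#' Read an ESRI ASCII grid
#'
#' Parses the standard 6-line header (ncols, nrows, xllcorner, yllcorner,
#' cellsize, NODATA_value) followed by whitespace-separated rows, north row
#' first. `negate = TRUE` flips the sign of all values on input: GEBCO-style
#' exports store elevation (negative at sea), whereas this package uses
#' positive-down depth throughout.
#'
#' @param path file path.
#' @param negate negate values on read (for elevation-convention exports).
#' @return a [habitat_raster].
#' @export
read_ascii_grid <- function(path, negate = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7) stop(path, ": too short for an ESRI ASCII grid")
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2)
      stop(path, ": malformed header line ", i, ": '", lines[i], "'")
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  missing <- setdiff(need, names(hdr))
  if (length(missing))
    stop(path, ": header missing field(s): ", paste(missing, collapse = ", "))
  nc <- hdr$ncols; nr <- hdr$nrows
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nr)
    stop(path, ": header declares ", nr, " rows but file has ", length(body))
  vals <- matrix(NA_real_, nrow = nr, ncol = nc)
  for (i in seq_len(nr)) {
    row <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "\\s+")[[1]]))
    if (length(row) != nc)
      stop(path, ": data row ", i, " has ", length(row), " values, expected ", nc)
    if (anyNA(row))
      stop(path, ": non-numeric value in data row ", i)
    vals[i, ] <- row
  }
  vals[vals == hdr$nodata_value] <- NA_real_
  if (negate) vals <- -vals
  habitat_raster(vals, hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
                 hdr$nodata_value)
}

#' Write an ESRI ASCII grid
#'
#' @param raster a [habitat_raster].
#' @param path output file path.
#' @param digits significant digits for cell values.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(raster, path, digits = 6) {
  stopifnot(inherits(raster, "habitat_raster"))
  vals <- raster$values
  vals[is.na(vals)] <- raster$nodata_value
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", raster$ncols),
    paste("nrows", raster$nrows),
    paste("xllcorner", format(raster$xll, digits = 12)),
    paste("yllcorner", format(raster$yll, digits = 12)),
    paste("cellsize", format(raster$cellsize, digits = 12)),
    paste("NODATA_value", raster$nodata_value)), con)
  for (i in seq_len(raster$nrows))
    writeLines(paste(signif(vals[i, ], digits), collapse = " "), con)
  invisible(path)
}
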