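# Small in-code fixtures shared across test files.

utc <- function(x) as.POSIXct(x, tz = "UTC")

# flat raster helper: constant value everywhere
flat_raster <- function(value, ncols = 20, nrows = 20, xll = -11, yll = 51,
                        cellsize = 0.01) {
  habitat_raster(matrix(value, nrows, ncols), xll, yll, cellsize)
}

make_fixes <- function(seal_id, t, lon, lat, nsat = 8L) {
  data.frame(seal_id = seal_id, timestamp = t, lon = lon, lat = lat,
             n_satellites = rep_len(nsat, length(t)))
}

# dives defined by midpoint time and a span; depth/duration filled plausibly
make_dives <- function(seal_id, t_mid, span_s = 120, max_depth_m = 60) {
  data.frame(seal_id = seal_id,
             start_time = t_mid - span_s / 2,
             end_time = t_mid + span_s / 2,
             max_depth_m = rep_len(max_depth_m, length(t_mid)),
             duration_s = rep_len(span_s, length(t_mid)))
}

# annotated-dive table straight from vectors, for classifier/summary tests
make_annotated <- function(max_depth_m, bathy_depth_m,
                           seal_id = "s1", sediment = "fine", diel = "day",
                           t0 = utc("2009-06-01 00:00:00")) {
  n <- max(length(max_depth_m), length(bathy_depth_m))
  data.frame(seal_id = rep_len(seal_id, n),
             start_time = t0 + (seq_len(n) - 1) * 600,
             end_time = t0 + (seq_len(n) - 1) * 600 + 120,
             max_depth_m = rep_len(max_depth_m, n),
             duration_s = 120,
             lon = -10.5, lat = 52.1,
             bathy_depth_m = rep_len(bathy_depth_m, n),
             sediment = rep_len(sediment, n),
             diel = rep_len(diel, n))
}
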