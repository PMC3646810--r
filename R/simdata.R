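#' Default pelagic-dive probabilities by sediment and diel period
#'
#' Probability that a deep-water (charted depth >= 50 m) dive is pelagic
#' rather than benthic, per pooled sediment class and day/night. Defaults for
#' the three mapped classes follow the field pattern the pipeline is designed
#' to recover: pelagic diving most frequent over fine sediment, least over
#' rock, and more frequent at night everywhere. The unclassified class gets
#' the across-sediment day/night averages.
#'
#' @return 4 x 2 numeric matrix, rows fine/coarse/rock/unclassified, columns
#'   day/night.
#' @export
default_p_pelagic <- function() {
  m <- rbind(fine = c(0.36, 0.52),
             coarse = c(0.28, 0.39),
             rock = c(0.20, 0.39),
             unclassified = c(0.28, 0.43))
  colnames(m) <- DIEL_LEVELS
  m
}

#' Simulation configuration
#'
#' Bundles and validates every tunable of the synthetic seal-track generator.
#' Durations are exponential (dive durations shifted so no dive is shorter
#' than the 8-s detection floor); GPS fixes are attempted on a fixed 30-min
#' schedule and succeed only while the animal is at the surface.
#'
#' @param n_seals number of animals.
#' @param deployment_days days of data per animal.
#' @param fix_interval_s interval between GPS fix attempts (default 1800 s,
#'   i.e. 30 min).
#' @param mean_dive_duration_s,mean_surface_duration_s means of the dive and
#'   post-dive surface intervals (seconds).
#' @param swim_speed_mps cruising speed of the correlated random walk; must
#'   stay below `max_speed_mps`.
#' @param max_speed_mps ceiling on plausible swim speed (the `s` of the
#'   interpolation-error bound); used for validation only.
#' @param turn_sd_rad SD of the per-cycle heading increment; 0 gives
#'   straight-line movement.
#' @param p_pelagic 4 x 2 matrix as [default_p_pelagic()].
#' @param gps_noise_m isotropic GPS error SD (metres) added to emitted fixes.
#' @param p_fix_success probability a surface-coincident fix attempt succeeds.
#' @param satellite_probs named numeric vector of satellite-count
#'   probabilities; default uniform over 4..10 so the >= 5 quality filter
#'   removes a nontrivial fraction.
#' @param rng_seed integer seed applied once per dataset; NULL = ambient RNG.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_seals = 8,
                       deployment_days = 7,
                       fix_interval_s = 1800,
                       mean_dive_duration_s = 180,
                       mean_surface_duration_s = 90,
                       swim_speed_mps = 0.8,
                       max_speed_mps = 2,
                       turn_sd_rad = 0.4,
                       p_pelagic = default_p_pelagic(),
                       gps_noise_m = 12,
                       p_fix_success = 0.9,
                       satellite_probs = setNames(rep(1 / 7, 7), 4:10),
                       rng_seed = NULL) {
  stopifnot(n_seals >= 1, deployment_days > 0, fix_interval_s > 0,
            mean_dive_duration_s > 8, mean_surface_duration_s > 0,
            swim_speed_mps > 0, max_speed_mps > 0, turn_sd_rad >= 0,
            gps_noise_m >= 0)
  if (p_fix_success < 0 || p_fix_success > 1)
    stop("p_fix_success must be in [0, 1]")
  if (swim_speed_mps > max_speed_mps)
    stop("swim_speed_mps must not exceed max_speed_mps")
  if (!is.matrix(p_pelagic) ||
      !identical(sort(rownames(p_pelagic)), sort(SEDIMENT_LEVELS)) ||
      !identical(colnames(p_pelagic), DIEL_LEVELS))
    stop("p_pelagic must be a matrix with rows ",
         paste(SEDIMENT_LEVELS, collapse = "/"), " and columns day/night")
  if (any(p_pelagic < 0 | p_pelagic > 1))
    stop("p_pelagic entries must be probabilities in [0, 1]")
  if (is.null(names(satellite_probs)) ||
      any(is.na(suppressWarnings(as.integer(names(satellite_probs))))))
    stop("satellite_probs must be named by integer satellite counts")
  if (any(satellite_probs < 0) || sum(satellite_probs) <= 0)
    stop("satellite_probs must be non-negative and sum > 0")
  structure(list(
    n_seals = as.integer(n_seals),
    deployment_days = deployment_days,
    fix_interval_s = fix_interval_s,
    mean_dive_duration_s = mean_dive_duration_s,
    mean_surface_duration_s = mean_surface_duration_s,
    swim_speed_mps = swim_speed_mps,
    max_speed_mps = max_speed_mps,
    turn_sd_rad = turn_sd_rad,
    p_pelagic = p_pelagic[SEDIMENT_LEVELS, , drop = FALSE],
    gps_noise_m = gps_noise_m,
    p_fix_success = p_fix_success,
    satellite_probs = satellite_probs / sum(satellite_probs),
    rng_seed = rng_seed), class = "sim_config")
}

#' Generate paired synthetic bathymetry and sediment rasters
#'
#' Bathymetry is a smooth west-to-east offshore gradient from 0 m at the
#' western edge to `max_depth_m`, plus low-amplitude smooth noise (clamped at
#' 0). Sediment is a patchy mosaic: each cell takes the class of its nearest
#' random seed point, giving contiguous blobs of fine/coarse/rock/unclassified
#' seabed. Both rasters share geometry exactly.
#'
#' @param seed RNG seed for reproducibility.
#' @param ncols,nrows grid dimensions (>= 16 each).
#' @param cellsize cell size in decimal degrees (default 0.003, the working
#'   resolution of predictive seabed sediment maps).
#' @param origin lon/lat of the lower-left corner.
#' @param max_depth_m depth at the offshore edge.
#' @param n_patches number of sediment seed points.
#' @return list with elements `depth` and `sediment`, both [habitat_raster].
#' @export
generate_habitat <- function(seed = 1, ncols = 128, nrows = 128,
                             cellsize = 0.003, origin = c(-10.8, 51.6),
                             max_depth_m = 350, n_patches = 40) {
  if (ncols < 16 || nrows < 16) stop("grid must be at least 16 x 16")
  if (max_depth_m < 300)
    warning("max_depth_m below 300 m gives an unrealistically shallow shelf")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  # offshore gradient along x with smooth sinusoidal perturbation
  x <- matrix(rep((seq_len(ncols) - 1) / (ncols - 1), each = nrows),
              nrow = nrows)
  y <- matrix(rep((seq_len(nrows) - 1) / (nrows - 1), times = ncols),
              nrow = nrows)
  depth <- max_depth_m * x^1.2
  for (k in 1:4) {
    fx <- runif(1, 1, 4); fy <- runif(1, 1, 4); ph <- runif(2, 0, 2 * pi)
    depth <- depth + max_depth_m * 0.02 *
      sin(2 * pi * fx * x + ph[1]) * sin(2 * pi * fy * y + ph[2])
  }
  depth <- pmax(depth, 0)
  depth[, 1] <- 0  # shoreline column

  # nearest-seed (Voronoi) sediment mosaic over codes 0..3
  sx <- runif(n_patches); sy <- runif(n_patches)
  scls <- sample(0:3, n_patches, replace = TRUE)
  sed <- matrix(0, nrow = nrows, ncol = ncols)
  for (j in seq_len(ncols)) {
    dx2 <- (sx - (j - 1) / (ncols - 1))^2
    for (i in seq_len(nrows)) {
      d2 <- dx2 + (sy - (i - 1) / (nrows - 1))^2
      sed[i, j] <- scls[which.min(d2)]
    }
  }

  list(depth = habitat_raster(depth[nrows:1, , drop = FALSE],
                              origin[1], origin[2], cellsize),
       sediment = habitat_raster(sed[nrows:1, , drop = FALSE],
                                 origin[1], origin[2], cellsize))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed",
                                                       envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# metres per degree of latitude / longitude at reference latitude
M_PER_DEG_LAT <- 111132
m_per_deg_lon <- function(lat) 111320 * cos(lat * DEG2RAD)

#' Simulate one seal's track, fixes and dives
#'
#' Event-driven correlated random walk over the habitat rasters. The animal
#' alternates surface intervals and dives (exponential durations; dives
#' shifted to respect the 8-s detection floor). GPS fixes are attempted on the
#' fixed `fix_interval_s` schedule and emitted only when the attempt falls in
#' a surface interval and a `p_fix_success` coin succeeds; emitted positions
#' get isotropic Gaussian noise of SD `gps_noise_m` and a satellite count from
#' the configured distribution. True dive type is drawn from local habitat:
#' water shallower than 50 m gives a "shallow" dive no deeper than the local
#' bottom; deeper water gives a pelagic dive (depth uniform in 10-90% of the
#' water column) with probability `p_pelagic[sediment, diel]`, otherwise a
#' benthic dive reaching 95-100% of the bottom depth.
#'
#' @param config a [sim_config].
#' @param depth,sediment [habitat_raster]s sharing geometry.
#' @param seal_id identifier written into the outputs.
#' @param start_time POSIXct UTC deployment start.
#' @param start_lon,start_lat optional release position; must fall on a data
#'   cell. Default: a random cell with charted depth >= 60 m.
#' @return list with data.frames `fixes` (seal_id, timestamp, lon, lat,
#'   n_satellites) and `truth` (seal_id, start_time, end_time, max_depth_m,
#'   duration_s, true_lon, true_lat, true_type).
#' @export
simulate_seal <- function(config, depth, sediment, seal_id = "seal1",
                          start_time = as.POSIXct("2009-03-01 00:00:00",
                                                  tz = "UTC"),
                          start_lon = NULL, start_lat = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!same_geometry(depth, sediment))
    stop("depth and sediment rasters must share geometry")
  ext <- raster_extent(depth)
  lat0 <- (ext["ymin"] + ext["ymax"]) / 2
  mlon <- m_per_deg_lon(lat0)

  # fast scalar cell lookup (row 1 of the matrix = north)
  cs <- depth$cellsize; nr <- depth$nrows; nc <- depth$ncols
  cell_val <- function(vals, lon, lat) {
    col <- floor((lon - depth$xll) / cs) + 1
    row_s <- floor((lat - depth$yll) / cs) + 1
    if (col < 1 || col > nc || row_s < 1 || row_s > nr) return(NA_real_)
    vals[nr - row_s + 1, col]
  }

  if (is.null(start_lon)) {
    deep <- which(!is.na(depth$values) & depth$values >= 60, arr.ind = TRUE)
    if (nrow(deep) == 0) stop("no cell with depth >= 60 m to release the seal")
    pick <- deep[sample.int(nrow(deep), 1), ]
    start_lon <- depth$xll + (pick[2] - 0.5) * cs
    start_lat <- depth$yll + (nr - pick[1] + 0.5) * cs
  }
  if (is.na(cell_val(depth$values, start_lon, start_lat)))
    stop("seal released on a nodata cell at (", start_lon, ", ", start_lat, ")")

  total_s <- config$deployment_days * 86400
  mean_cycle <- config$mean_surface_duration_s + config$mean_dive_duration_s
  n_guess <- ceiling(total_s / mean_cycle * 1.6) + 16

  f_time <- numeric(n_guess); f_lon <- numeric(n_guess)
  f_lat <- numeric(n_guess); f_sat <- integer(n_guess); nf <- 0L
  d_start <- numeric(n_guess); d_dur <- numeric(n_guess)
  d_depth <- numeric(n_guess); d_lon <- numeric(n_guess)
  d_lat <- numeric(n_guess); d_type <- character(n_guess); nd <- 0L

  sat_counts <- as.integer(names(config$satellite_probs))
  margin <- cs  # keep one cell off the boundary
  lon <- start_lon; lat <- start_lat
  heading <- runif(1, 0, 2 * pi)
  v <- config$swim_speed_mps
  t <- 0
  fix_k_next <- 0L  # next fix-attempt index (attempts at k * fix_interval)

  while (t < total_s) {
    surf_dur <- max(5, round(rexp(1, 1 / config$mean_surface_duration_s)))
    dive_dur <- max(9, round(8 + rexp(
      1, 1 / (config$mean_dive_duration_s - 8))))
    cycle <- surf_dur + dive_dur

    # one straight segment per cycle; turn at cycle start
    heading <- heading + if (config$turn_sd_rad > 0)
      rnorm(1, 0, config$turn_sd_rad) else 0
    for (try in 1:2) {
      step_m <- v * cycle
      nlon <- lon + step_m * cos(heading) / mlon
      nlat <- lat + step_m * sin(heading) / M_PER_DEG_LAT
      ok <- nlon > ext["xmin"] + margin && nlon < ext["xmax"] - margin &&
        nlat > ext["ymin"] + margin && nlat < ext["ymax"] - margin &&
        !is.na(cell_val(depth$values, nlon, nlat))
      if (ok) break
      heading <- heading + pi  # bounce back
    }
    if (!ok) { nlon <- lon; nlat <- lat; step_m <- 0 }
    dlon_dt <- (nlon - lon) / cycle
    dlat_dt <- (nlat - lat) / cycle

    # fix attempts falling inside the surface interval [t, t + surf_dur)
    while (fix_k_next * config$fix_interval_s < t)
      fix_k_next <- fix_k_next + 1L
    while ((ta <- fix_k_next * config$fix_interval_s) < t + surf_dur) {
      if (ta <= total_s && runif(1) < config$p_fix_success) {
        nf <- nf + 1L
        f_time[nf] <- ta
        f_lon[nf] <- lon + dlon_dt * (ta - t) +
          rnorm(1, 0, config$gps_noise_m) / mlon
        f_lat[nf] <- lat + dlat_dt * (ta - t) +
          rnorm(1, 0, config$gps_noise_m) / M_PER_DEG_LAT
        f_sat[nf] <- sample(sat_counts, 1, prob = config$satellite_probs)
      }
      fix_k_next <- fix_k_next + 1L
    }

    # dive at the back of the cycle; truth anchored at its temporal midpoint
    t_mid <- t + surf_dur + dive_dur / 2
    p_lon <- lon + dlon_dt * (t_mid - t)
    p_lat <- lat + dlat_dt * (t_mid - t)
    wd <- cell_val(depth$values, p_lon, p_lat)
    if (!is.na(wd) && wd >= 2 && t + cycle <= total_s) {
      if (wd < 50) {
        type <- "shallow"
        md <- runif(1, 1.6, wd)
      } else {
        sed <- sediment_from_code(cell_val(sediment$values, p_lon, p_lat))
        diel <- .is_day_scalar(start_time, t + surf_dur, p_lon, p_lat)
        if (runif(1) < config$p_pelagic[sed, diel]) {
          type <- "pelagic"
          md <- runif(1, 0.1, 0.9) * wd
        } else {
          type <- "benthic"
          md <- runif(1, 0.95, 1.0) * wd
        }
      }
      nd <- nd + 1L
      d_start[nd] <- t + surf_dur
      d_dur[nd] <- dive_dur
      d_depth[nd] <- md
      d_lon[nd] <- p_lon
      d_lat[nd] <- p_lat
      d_type[nd] <- type
    }

    lon <- nlon; lat <- nlat
    t <- t + cycle
  }

  fixes <- data.frame(
    seal_id = rep(seal_id, nf),
    timestamp = start_time + f_time[seq_len(nf)],
    lon = f_lon[seq_len(nf)], lat = f_lat[seq_len(nf)],
    n_satellites = f_sat[seq_len(nf)])
  truth <- data.frame(
    seal_id = rep(seal_id, nd),
    start_time = start_time + d_start[seq_len(nd)],
    end_time = start_time + d_start[seq_len(nd)] + d_dur[seq_len(nd)],
    max_depth_m = d_depth[seq_len(nd)],
    duration_s = d_dur[seq_len(nd)],
    true_lon = d_lon[seq_len(nd)], true_lat = d_lat[seq_len(nd)],
    true_type = d_type[seq_len(nd)])
  list(fixes = fixes, truth = truth)
}

# cheap scalar day/night used inside the simulator loop
.is_day_scalar <- function(start_time, offset_s, lon, lat) {
  if (solar_zenith(start_time + offset_s, lon, lat) < SUNRISE_ZENITH_DEG)
    "day" else "night"
}

#' Simulate a multi-seal dataset
#'
#' Runs [simulate_seal] once per animal (ids `seal01`, `seal02`, ...) and
#' returns the combined tables. If `config$rng_seed` is set, all randomness
#' is reproducible from that single seed.
#'
#' @param config a [sim_config].
#' @param depth,sediment [habitat_raster]s sharing geometry.
#' @param start_time deployment start, POSIXct UTC.
#' @return list with `fixes`, `dives` (the observation table: no truth
#'   columns) and `truth` data.frames.
#' @export
simulate_dataset <- function(config, depth, sediment,
                             start_time = as.POSIXct("2009-03-01 00:00:00",
                                                     tz = "UTC")) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  ids <- sprintf("seal%02d", seq_len(config$n_seals))
  sims <- lapply(ids, function(id)
    simulate_seal(config, depth, sediment, seal_id = id,
                  start_time = start_time))
  fixes <- do.call(rbind, lapply(sims, `[[`, "fixes"))
  truth <- do.call(rbind, lapply(sims, `[[`, "truth"))
  dives <- truth[, c("seal_id", "start_time", "end_time", "max_depth_m",
                     "duration_s")]
  rownames(fixes) <- rownames(truth) <- rownames(dives) <- NULL
  list(fixes = fixes, dives = dives, truth = truth)
}

#' Write a simulated dataset to CSV
#'
#' Emits `fixes.csv`, `dives.csv` and `truth.csv` into `dir` with ISO-8601
#' UTC timestamps. Inputs are validated before any file is touched, so a bad
#' call leaves no partial output.
#'
#' @param fixes,dives,truth data.frames as returned by [simulate_dataset].
#' @param dir output directory (created if needed).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_dataset <- function(fixes, dives, truth, dir) {
  if (is.null(fixes) || nrow(fixes) == 0) stop("no fixes to write")
  if (is.null(dives) || nrow(dives) == 0) stop("no dives to write")
  if (is.null(truth) || nrow(truth) == 0) stop("no truth records to write")
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  paths <- c(fixes = file.path(dir, "fixes.csv"),
             dives = file.path(dir, "dives.csv"),
             truth = file.path(dir, "truth.csv"))
  fx <- fixes; fx$timestamp <- format_utc(fx$timestamp)
  dv <- dives
  dv$start_time <- format_utc(dv$start_time)
  dv$end_time <- format_utc(dv$end_time)
  tr <- truth
  tr$start_time <- format_utc(tr$start_time)
  tr$end_time <- format_utc(tr$end_time)
  write.csv(fx, paths["fixes"], row.names = FALSE, quote = FALSE)
  write.csv(dv, paths["dives"], row.names = FALSE, quote = FALSE)
  write.csv(tr, paths["truth"], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

format_utc <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

parse_utc <- function(x) {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  plain <- is.na(out) & !is.na(x)
  if (any(plain))  # tolerate "YYYY-mm-dd HH:MM:SS"; anything else stays NA
    out[plain] <- as.POSIXct(x[plain], format = "%Y-%m-%d %H:%M:%S",
                             tz = "UTC")
  out
}
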