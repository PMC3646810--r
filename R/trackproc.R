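#' Great-circle distance
#'
#' Haversine distance in metres on a sphere of radius 6371 km. Vectorized.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees.
#' @return distances in metres.
#' @export
haversine_m <- function(lon1, lat1, lon2, lat2) {
  r <- 6371000
  p1 <- lat1 * DEG2RAD; p2 <- lat2 * DEG2RAD
  dp <- (lat2 - lat1) * DEG2RAD; dl <- (lon2 - lon1) * DEG2RAD
  a <- sin(dp / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Quality-filter GPS fixes
#'
#' Keeps fixes that used at least `min_satellites` satellites (default 5,
#' the standard Fastloc quality cut), sorts by seal and time, and collapses
#' duplicate timestamps within a seal to the fix with the most satellites.
#'
#' @param fixes data.frame with columns seal_id, timestamp (POSIXct),
#'   lon, lat, n_satellites.
#' @param min_satellites inclusive threshold.
#' @return filtered data.frame, with attribute `n_dropped` (fixes removed by
#'   the satellite cut plus de-duplication).
#' @export
filter_fixes <- function(fixes, min_satellites = 5) {
  req <- c("seal_id", "timestamp", "lon", "lat", "n_satellites")
  miss <- setdiff(req, names(fixes))
  if (length(miss)) stop("fixes missing column(s): ", paste(miss, collapse = ", "))
  n_in <- nrow(fixes)
  keep <- fixes[!is.na(fixes$n_satellites) &
                  fixes$n_satellites >= min_satellites, , drop = FALSE]
  # order so that, within duplicate timestamps, the best fix comes first
  keep <- keep[order(keep$seal_id, keep$timestamp, -keep$n_satellites), ,
               drop = FALSE]
  dup <- duplicated(keep[, c("seal_id", "timestamp")])
  keep <- keep[!dup, , drop = FALSE]
  rownames(keep) <- NULL
  attr(keep, "n_dropped") <- n_in - nrow(keep)
  keep
}

#' Interpolate a position for every dive
#'
#' Anchors each dive at its temporal midpoint and linearly interpolates
#' longitude and latitude independently between the bracketing retained fixes
#' (straight-line interpolation; valid at the km scale of 30-min fix gaps).
#' Dives whose midpoint falls before a seal's first fix or after its last are
#' dropped, as are all dives of seals with fewer than two fixes; drop counts
#' are attached as attributes.
#'
#' @param fixes filtered fixes ([filter_fixes] output).
#' @param dives data.frame with seal_id, start_time, end_time, max_depth_m,
#'   duration_s.
#' @return dives with added `lon`, `lat` columns; attributes
#'   `n_dropped_outside` (midpoint outside the fix envelope) and
#'   `n_dropped_no_track` (seal had < 2 fixes).
#' @export
interpolate_dive_locations <- function(fixes, dives) {
  req <- c("seal_id", "start_time", "end_time")
  miss <- setdiff(req, names(dives))
  if (length(miss)) stop("dives missing column(s): ", paste(miss, collapse = ", "))
  dives <- dives[order(dives$seal_id, dives$start_time), , drop = FALSE]
  t_mid <- as.numeric(dives$start_time) +
    (as.numeric(dives$end_time) - as.numeric(dives$start_time)) / 2
  lon <- rep(NA_real_, nrow(dives)); lat <- rep(NA_real_, nrow(dives))
  n_no_track <- 0L
  for (id in unique(dives$seal_id)) {
    di <- which(dives$seal_id == id)
    fx <- fixes[fixes$seal_id == id, , drop = FALSE]
    if (nrow(fx) < 2) {
      warning("seal ", id, ": fewer than 2 retained fixes; ",
              length(di), " dive(s) dropped")
      n_no_track <- n_no_track + length(di)
      next
    }
    ft <- as.numeric(fx$timestamp)
    lon[di] <- approx(ft, fx$lon, xout = t_mid[di], rule = 1, ties = "ordered")$y
    lat[di] <- approx(ft, fx$lat, xout = t_mid[di], rule = 1, ties = "ordered")$y
  }
  dives$lon <- lon; dives$lat <- lat
  located <- !is.na(lon) & !is.na(lat)
  out <- dives[located, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_outside") <- sum(!located) - n_no_track
  attr(out, "n_dropped_no_track") <- n_no_track
  out
}

#' Interpolated-location error bound
#'
#' The extra positional uncertainty (beyond raw GPS error) of interpolated
#' dive locations, operationalized as the potential travel distance in a mean
#' fix gap minus the distance actually covered, spread over the dive cycles
#' in the gap:
#' \deqn{e = (s_{max} \bar t - \bar d) / \bar n, \qquad
#'       \bar n = \bar t / (\bar{dur}_{dive} + \bar{dur}_{surface})}
#' where \eqn{\bar t} is the mean inter-fix time gap (s), \eqn{\bar d} the
#' mean inter-fix great-circle distance (m) and \eqn{s_{max}} the maximum
#' swimming speed observed between successive fixes. \eqn{\bar n} below 1 is
#' clamped to 1 with a warning. Computed per seal and pooled over all seals
#' (pooled \eqn{s_{max}} = overall maximum). The published form of this bound
#' is not fully recoverable, so the exact expression is isolated here as the
#' single point of change.
#'
#' @param fixes filtered fixes.
#' @param dives dive table used to estimate mean dive/surface durations when
#'   not supplied.
#' @param mean_dive_duration_s,mean_surface_duration_s optional overrides for
#'   the cycle components (seconds).
#' @return list with `per_seal` (data.frame: seal_id, t_bar_s, d_bar_m,
#'   s_max_mps, n_bar, error_m) and `pooled` (one-row data.frame).
#' @export
interpolation_error <- function(fixes, dives,
                                mean_dive_duration_s = NULL,
                                mean_surface_duration_s = NULL) {
  if (is.null(mean_dive_duration_s))
    mean_dive_duration_s <- mean(dives$duration_s)
  if (is.null(mean_surface_duration_s)) {
    gaps <- unlist(lapply(split(dives, dives$seal_id), function(d) {
      d <- d[order(d$start_time), ]
      as.numeric(d$start_time[-1]) - as.numeric(d$end_time[-nrow(d)])
    }))
    gaps <- gaps[gaps > 0]
    if (!length(gaps)) stop("cannot estimate mean surface duration from dives")
    mean_surface_duration_s <- mean(gaps)
  }
  stopifnot(mean_dive_duration_s > 0, mean_surface_duration_s > 0)
  cycle <- mean_dive_duration_s + mean_surface_duration_s

  gap_stats <- function(fx) {
    fx <- fx[order(fx$timestamp), ]
    n <- nrow(fx)
    if (n < 2) return(NULL)
    dt <- diff(as.numeric(fx$timestamp))
    dd <- haversine_m(fx$lon[-n], fx$lat[-n], fx$lon[-1], fx$lat[-1])
    pos <- dt > 0
    list(dt = dt[pos], dd = dd[pos])
  }
  eval_error <- function(dt, dd) {
    t_bar <- mean(dt); d_bar <- mean(dd); s_max <- max(dd / dt)
    n_bar <- t_bar / cycle
    if (n_bar < 1) {
      warning("mean dive cycles per fix gap < 1; clamped to 1")
      n_bar <- 1
    }
    data.frame(t_bar_s = t_bar, d_bar_m = d_bar, s_max_mps = s_max,
               n_bar = n_bar, error_m = (s_max * t_bar - d_bar) / n_bar)
  }

  per <- lapply(split(fixes, fixes$seal_id), gap_stats)
  per <- per[!vapply(per, is.null, logical(1))]
  if (!length(per)) stop("no seal has >= 2 fixes; cannot compute error bound")
  per_seal <- do.call(rbind, lapply(names(per), function(id)
    cbind(seal_id = id, eval_error(per[[id]]$dt, per[[id]]$dd))))
  rownames(per_seal) <- NULL
  pooled <- eval_error(unlist(lapply(per, `[[`, "dt")),
                       unlist(lapply(per, `[[`, "dd")))
  list(per_seal = per_seal, pooled = pooled,
       mean_dive_duration_s = mean_dive_duration_s,
       mean_surface_duration_s = mean_surface_duration_s)
}
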