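#' Dive-classifier configuration
#'
#' @param shallow_cutoff_m charted-depth cutoff below which dives are labelled
#'   "shallow" (default 50 m, where charted-depth error makes the proximity
#'   ratio unreliable).
#' @param benthic_ratio proximity-ratio threshold at and above which a deep
#'   dive is "benthic" (default 0.95).
#' @return list of class `classifier_config`.
#' @export
classifier_config <- function(shallow_cutoff_m = 50, benthic_ratio = 0.95) {
  stopifnot(shallow_cutoff_m > 0,
            benthic_ratio > 0, benthic_ratio <= 1)
  structure(list(shallow_cutoff_m = shallow_cutoff_m,
                 benthic_ratio = benthic_ratio),
            class = "classifier_config")
}

#' Proximity-to-benthos ratio
#'
#' Maximum dive depth divided by charted bathymetric depth. Values above 1
#' (dive apparently deeper than the chart, from charted-depth or position
#' error) are retained, not clipped. Non-positive or missing charted depth
#' yields `NA`.
#'
#' @param max_depth_m maximum dive depth (m).
#' @param bathy_depth_m charted water depth (m, positive down).
#' @return numeric vector of ratios.
#' @export
proximity_ratio <- function(max_depth_m, bathy_depth_m) {
  out <- max_depth_m / bathy_depth_m
  out[is.na(bathy_depth_m) | bathy_depth_m <= 0] <- NA_real_
  out
}

#' Classify dives as shallow, pelagic or benthic
#'
#' Charted depth below the shallow cutoff gives "shallow" regardless of dive
#' depth; otherwise the proximity ratio decides: below `benthic_ratio` is
#' "pelagic", at or above it (including ratios over 1) is "benthic". Dives
#' with missing charted depth are left `NA` and counted in attribute
#' `n_unclassifiable`.
#'
#' @param dives annotated dives ([annotate_dives] output).
#' @param cfg a [classifier_config].
#' @return dives with added `ratio` and `dive_type` columns and attribute
#'   `n_unclassifiable`.
#' @export
classify_dives <- function(dives, cfg = classifier_config()) {
  if (!"bathy_depth_m" %in% names(dives))
    stop("dives missing column(s): bathy_depth_m (run annotate_dives first)")
  stopifnot(inherits(cfg, "classifier_config"))
  ratio <- proximity_ratio(dives$max_depth_m, dives$bathy_depth_m)
  type <- rep(NA_character_, nrow(dives))
  has_bathy <- !is.na(dives$bathy_depth_m) & dives$bathy_depth_m > 0
  shallow <- has_bathy & dives$bathy_depth_m < cfg$shallow_cutoff_m
  deep <- has_bathy & !shallow
  type[shallow] <- "shallow"
  type[deep & ratio < cfg$benthic_ratio] <- "pelagic"
  type[deep & ratio >= cfg$benthic_ratio] <- "benthic"
  dives$ratio <- ratio
  dives$dive_type <- type
  attr(dives, "n_unclassifiable") <- sum(!has_bathy)
  dives
}

#' Charted-depth error diagnostic
#'
#' Reproduces the threshold-setting diagnostic: bins dives by charted depth
#' into `[0,5), [5,10), ...` metre intervals and reports, per bin, the number
#' of dives and the proportion whose proximity ratio exceeds 1 -- an
#' unambiguous signature of charted-depth error, expected to fade with depth.
#' The full empirical ratio distribution is returned alongside for threshold
#' inspection.
#'
#' @param dives annotated dives with `max_depth_m` and `bathy_depth_m`.
#' @param bin_width_m depth bin width (default 5 m).
#' @return list of class `ratio_diagnostic`: `table` (bin_lo, bin_hi, n,
#'   prop_gt1) and `ratios` (all finite proximity ratios).
#' @export
ratio_error_diagnostic <- function(dives, bin_width_m = 5) {
  ratio <- proximity_ratio(dives$max_depth_m, dives$bathy_depth_m)
  ok <- !is.na(ratio) & !is.na(dives$bathy_depth_m)
  if (!sum(ok)) stop("no dives with usable charted depth")
  bd <- dives$bathy_depth_m[ok]; r <- ratio[ok]
  bin <- floor(bd / bin_width_m)
  tab <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    data.frame(bin_lo = b * bin_width_m, bin_hi = (b + 1) * bin_width_m,
               n = sum(sel), prop_gt1 = mean(r[sel] > 1))
  }))
  structure(list(table = tab, ratios = r), class = "ratio_diagnostic")
}

#' @export
print.ratio_diagnostic <- function(x, ...) {
  cat("Proximity-ratio diagnostic (", nrow(x$table), " depth bins, ",
      length(x$ratios), " dives)\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}
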