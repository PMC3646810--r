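#' Pelagic-dive frequency per seal, sediment and diel period
#'
#' For each seal x mapped-sediment x day/night cell, the proportion of dives
#' that were pelagic. Dives over unclassified sediment are excluded (the
#' analysis concerns mapped seabed only). The denominator is either all
#' classified dives (`"all"`, matching "frequency of pelagic dives out of all
#' dives over mapped substrate") or deep dives only (`"deep"`:
#' pelagic + benthic, the subset for which the pelagic/benthic distinction is
#' defined). Cells with no dives are omitted.
#'
#' @param dives classified dives ([classify_dives] output).
#' @param denominator `"all"` or `"deep"`.
#' @return data.frame with seal_id, sediment, diel, n_dives, n_pelagic, freq.
#' @export
pelagic_frequency_table <- function(dives, denominator = c("all", "deep")) {
  denominator <- match.arg(denominator)
  req <- c("seal_id", "sediment", "diel", "dive_type")
  miss <- setdiff(req, names(dives))
  if (length(miss)) stop("dives missing column(s): ", paste(miss, collapse = ", "))
  d <- dives[!is.na(dives$dive_type) &
               dives$sediment %in% c("fine", "coarse", "rock"), , drop = FALSE]
  if (denominator == "deep")
    d <- d[d$dive_type %in% c("pelagic", "benthic"), , drop = FALSE]
  if (!nrow(d))
    return(data.frame(seal_id = character(0), sediment = character(0),
                      diel = character(0), n_dives = integer(0),
                      n_pelagic = integer(0), freq = numeric(0)))
  key <- interaction(d$seal_id, d$sediment, d$diel, drop = TRUE)
  parts <- split(d, key)
  out <- do.call(rbind, lapply(parts, function(p) data.frame(
    seal_id = p$seal_id[1], sediment = p$sediment[1], diel = p$diel[1],
    n_dives = nrow(p), n_pelagic = sum(p$dive_type == "pelagic"))))
  out$freq <- out$n_pelagic / out$n_dives
  out <- out[order(out$seal_id, out$sediment, out$diel), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Linear model of pelagic-dive frequency
#'
#' Ordinary least squares of per-cell pelagic frequency on sediment class,
#' diel period and individual (the individual term absorbs non-independence
#' of cells from the same seal), with sequential (type-I) ANOVA F tests in
#' that order. No interaction by default. A factor observed at fewer than two
#' levels is dropped with a message rather than fit rank-deficiently.
#'
#' @param cells output of [pelagic_frequency_table].
#' @param include_interaction add the sediment x diel interaction term.
#' @return list of class `pelagic_freq_model`: `fit` (the `lm`), `anova`
#'   (sequential table), `r_squared`, `cell_means` (sediment x diel mean,
#'   across-seal SE and n), `dropped` (any dropped terms).
#' @export
fit_frequency_model <- function(cells, include_interaction = FALSE) {
  stopifnot(nrow(cells) >= 3)
  d <- cells
  d$sediment <- factor(d$sediment, levels = c("fine", "coarse", "rock"))
  d$sediment <- droplevels(d$sediment)
  d$diel <- factor(d$diel, levels = DIEL_LEVELS)
  d$diel <- droplevels(d$diel)
  d$seal_id <- factor(d$seal_id)
  terms <- c("sediment", "diel", "seal_id")
  dropped <- character(0)
  for (tm in terms) {
    if (nlevels(d[[tm]]) < 2) {
      message("term '", tm, "' has a single level; dropped from the model")
      dropped <- c(dropped, tm)
    }
  }
  terms <- setdiff(terms, dropped)
  if (!length(terms)) stop("no factor with >= 2 levels; nothing to fit")
  rhs <- paste(terms, collapse = " + ")
  if (include_interaction && all(c("sediment", "diel") %in% terms))
    rhs <- paste(rhs, "+ sediment:diel")
  fit <- lm(stats::as.formula(paste("freq ~", rhs)), data = d)
  av <- anova(fit)
  r2 <- summary(fit)$r.squared
  if (sum((d$freq - mean(d$freq))^2) < 1e-12) {
    # constant response: nothing to explain, report zeros rather than 0/0
    r2 <- 0
    av[["F value"]][!is.na(av[["F value"]])] <- 0
    av[["Pr(>F)"]][!is.na(av[["Pr(>F)"]])] <- 1
  }

  agg_mean <- aggregate(freq ~ sediment + diel, data = d, FUN = mean)
  agg_sd <- aggregate(freq ~ sediment + diel, data = d, FUN = sd)
  agg_n <- aggregate(freq ~ sediment + diel, data = d, FUN = length)
  cm <- agg_mean
  names(cm)[3] <- "mean_freq"
  cm$se <- agg_sd$freq / sqrt(agg_n$freq)
  cm$n_seals <- agg_n$freq
  cm <- cm[order(cm$sediment, cm$diel), ]
  rownames(cm) <- NULL

  structure(list(fit = fit, anova = av, r_squared = r2, cell_means = cm,
                 dropped = dropped),
            class = "pelagic_freq_model")
}

#' @export
print.pelagic_freq_model <- function(x, ...) {
  cat(sprintf("Linear model of pelagic-dive frequency (R^2 = %.3f)\n",
              x$r_squared))
  print(x$anova)
  cat("\nCell means (+/- across-seal SE):\n")
  print(transform(x$cell_means,
                  mean_freq = round(mean_freq, 3), se = round(se, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Serializable report of a frequency model
#'
#' @param model a `pelagic_freq_model`.
#' @return plain list (suitable for JSON) with R-squared, per-term F/p and
#'   cell means.
#' @export
model_report <- function(model) {
  stopifnot(inherits(model, "pelagic_freq_model"))
  av <- model$anova
  terms <- rownames(av)[rownames(av) != "Residuals"]
  list(
    r_squared = model$r_squared,
    anova = lapply(setNames(terms, terms), function(tm) list(
      df = av[tm, "Df"],
      df_resid = av["Residuals", "Df"],
      f = av[tm, "F value"],
      p = av[tm, "Pr(>F)"])),
    cell_means = model$cell_means,
    dropped_terms = model$dropped)
}
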