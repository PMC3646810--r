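#' Temporal state sequence for one seal
#'
#' Extracts the time-ordered sequence of labels of `attribute` for a single
#' seal's classified dives. Input must already be sorted by start time (an
#' unsorted table is rejected rather than silently reordered). `NA` labels --
#' dives that could not be classified -- are removed; for sediment the
#' "unclassified" class is an ordinary retained state, so that transitions
#' between two mapped sediments interspersed by unmapped seabed are not
#' conflated with direct transitions.
#'
#' @param dives classified dives for one seal, time-sorted.
#' @param attribute `"dive_type"` or `"sediment"`.
#' @return character vector of labels in temporal order.
#' @export
state_sequence <- function(dives, attribute = c("dive_type", "sediment")) {
  attribute <- match.arg(attribute)
  if (length(unique(dives$seal_id)) > 1)
    stop("state_sequence expects dives of a single seal")
  if (is.unsorted(as.numeric(dives$start_time)))
    stop("dives must be sorted by start_time")
  lab <- dives[[attribute]]
  lab[!is.na(lab)]
}

#' Joint transition matrix of a label sequence
#'
#' Counts consecutive pairs (state at dive *i*, state at dive *i + 1*) and
#' normalizes by the total number of pairs, giving a joint pair-frequency
#' matrix whose entries sum to 1 over all cells. The row-conditional kernel
#' (rows renormalized to 1) is returned alongside for simulation-recovery
#' work.
#'
#' @param seq character vector of labels.
#' @param states ordered state labels; every label in `seq` must be among
#'   them.
#' @return list of class `joint_transitions`: `states`, `joint` (K x K,
#'   sums to 1), `conditional` (rows sum to 1 where visited), `n_pairs`.
#' @export
joint_transition_matrix <- function(seq, states) {
  if (length(seq) < 2) stop("need at least 2 labels to form pairs")
  bad <- setdiff(unique(seq), states)
  if (length(bad))
    stop("label(s) outside the state set: ", paste(bad, collapse = ", "))
  from <- factor(seq[-length(seq)], levels = states)
  to <- factor(seq[-1], levels = states)
  counts <- table(from = from, to = to)
  n_pairs <- length(seq) - 1L
  joint <- unclass(counts) / n_pairs
  rs <- rowSums(joint)
  conditional <- joint / ifelse(rs > 0, rs, 1)
  structure(list(states = states, joint = joint, conditional = conditional,
                 n_pairs = n_pairs), class = "joint_transitions")
}

#' Per-seal transition matrices
#'
#' Builds one joint transition matrix per seal over consecutive classified
#' dives. Pairs are formed only within a seal; seals with fewer than two
#' usable dives are excluded with a warning. Optionally stratifies by diel
#' period (pairs formed within each day/night subsequence).
#'
#' @param dives classified dives, all seals.
#' @param attribute `"dive_type"` or `"sediment"`.
#' @param states ordered state labels; defaults to the canonical set for the
#'   attribute.
#' @param by_diel if TRUE, returns a list with `day` and `night` elements,
#'   each a per-seal matrix list.
#' @return named list of [joint_transition_matrix] results, one per seal.
#' @export
transition_matrices <- function(dives,
                                attribute = c("dive_type", "sediment"),
                                states = NULL, by_diel = FALSE) {
  attribute <- match.arg(attribute)
  states <- states %||% switch(attribute,
    dive_type = DIVE_TYPES, sediment = SEDIMENT_LEVELS)
  if (by_diel) {
    return(lapply(setNames(DIEL_LEVELS, DIEL_LEVELS), function(dl)
      transition_matrices(dives[dives$diel == dl, , drop = FALSE],
                          attribute, states, by_diel = FALSE)))
  }
  out <- list()
  for (id in unique(dives$seal_id)) {
    d <- dives[dives$seal_id == id, , drop = FALSE]
    d <- d[order(d$start_time), , drop = FALSE]
    seq <- state_sequence(d, attribute)
    if (length(seq) < 2) {
      warning("seal ", id, ": fewer than 2 classified dives; excluded")
      next
    }
    out[[id]] <- joint_transition_matrix(seq, states)
  }
  out
}

#' Aggregate transition matrices across seals
#'
#' Cell-wise mean and dispersion of the per-seal joint matrices, each seal
#' weighted equally regardless of its dive count (the repeated-measures
#' safeguard: individuals, not dives, are the replicates). Differing state
#' sets are unioned, absent states contributing zeros.
#'
#' @param mats named list of [joint_transition_matrix] results (or bare
#'   matrices), one per seal.
#' @param dispersion `"sd"` (default, matching tabulated mean +/- SD
#'   reporting) or `"var"`.
#' @param sample use the n-1 (sample) denominator (default) rather than n.
#' @return list of class `transition_summary`: `states`, `per_seal` (list of
#'   joint matrices), `mean`, `dispersion`, `dispersion_type`, `n_pairs`.
#' @export
aggregate_across_seals <- function(mats, dispersion = c("sd", "var"),
                                   sample = TRUE) {
  dispersion <- match.arg(dispersion)
  if (!length(mats)) stop("no per-seal matrices to aggregate")
  get_joint <- function(m) if (inherits(m, "joint_transitions")) m$joint else m
  joints <- lapply(mats, get_joint)
  states <- Reduce(union, lapply(joints, rownames))
  k <- length(states)
  expand <- function(m) {
    full <- matrix(0, k, k, dimnames = list(from = states, to = states))
    full[rownames(m), colnames(m)] <- m
    full
  }
  joints <- lapply(joints, expand)
  arr <- simplify2array(joints)  # k x k x n_seals
  n <- length(joints)
  mu <- apply(arr, c(1, 2), mean)
  if (n > 1) {
    denom <- if (sample) n - 1 else n
    vr <- apply(arr, c(1, 2), function(v) sum((v - mean(v))^2) / denom)
  } else {
    vr <- matrix(0, k, k, dimnames = dimnames(mu))
  }
  disp <- if (dispersion == "sd") sqrt(vr) else vr
  n_pairs <- vapply(mats, function(m)
    if (inherits(m, "joint_transitions")) m$n_pairs else NA_integer_,
    numeric(1))
  structure(list(states = states, per_seal = joints, mean = mu,
                 dispersion = disp, dispersion_type = dispersion,
                 n_pairs = n_pairs),
            class = "transition_summary")
}

#' @export
print.transition_summary <- function(x, digits = 3, ...) {
  cat("Transition summary over", length(x$per_seal), "seal(s); states:",
      paste(x$states, collapse = ", "), "\n")
  cat("Mean joint pair frequencies:\n")
  print(round(x$mean, digits))
  cat("Dispersion (", x$dispersion_type, "):\n", sep = "")
  print(round(x$dispersion, digits))
  invisible(x)
}

#' Long-format export of a transition summary
#'
#' One row per (seal, from, to) plus `MEAN` and the dispersion rows --
#' the layout of the published transition tables.
#'
#' @param ts a `transition_summary`.
#' @return data.frame with columns seal_id, from_state, to_state, value.
#' @export
transitions_to_long <- function(ts) {
  stopifnot(inherits(ts, "transition_summary"))
  one <- function(id, m) {
    g <- expand.grid(from_state = rownames(m), to_state = colnames(m),
                     stringsAsFactors = FALSE)
    data.frame(seal_id = id, g, value = as.vector(m))
  }
  rows <- c(lapply(names(ts$per_seal), function(id) one(id, ts$per_seal[[id]])),
            list(one("MEAN", ts$mean),
                 one(toupper(ts$dispersion_type), ts$dispersion)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
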