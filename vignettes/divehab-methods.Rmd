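---
title: "Methods: dive classification, habitat annotation and behavioural transitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dive classification, habitat annotation and behavioural transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divehab)
```

## The model

A diving pinniped carrying a Fastloc-GPS/TDR tag produces two records: a
sparse, surface-conditional sequence of position fixes and a dense dive table
(start, end, maximum depth, duration; dives begin when the tag passes 1.5 m
for at least 8 s). The scientific object of interest is the **dive type** —
whether each dive terminated at the seabed (benthic foraging), in midwater
(pelagic), or in water too shallow for the distinction to be reliable — and
how dive type co-varies with seabed sediment and the day/night cycle, and
sequences over consecutive dives.

The classifier is deliberately simple and fully deterministic. With charted
water depth $B$ at the dive's location and maximum dive depth $D$:

$$\text{type} = \begin{cases}
\text{shallow} & B < 50\ \mathrm{m}\\
\text{pelagic} & B \ge 50,\ r = D/B < 0.95\\
\text{benthic} & B \ge 50,\ r \ge 0.95
\end{cases}$$

The 50 m gate and the 0.95 proximity threshold are the two tunables
(`classifier_config()`). Below ~50 m, tidal range and positional error are a
substantial fraction of the water column, visible as a high proportion of
ratios above 1; `ratio_error_diagnostic()` reproduces that check (proportion
of $r > 1$ per 5-m charted-depth bin, plus the empirical distribution of
$r$). Two boundary conventions had to be fixed because the source thresholds
("< 0.95 pelagic, > 0.95 benthic"; "deeper than 50 m") leave the equalities
unassigned: ratio exactly 0.95 is **benthic** (the benthic set is closed
below), and charted depth exactly 50 m is **classified** (the shallow set is
open above). Ratios above 1 are retained, not clipped — they carry the
charted-depth error signal.

## Locating dives

Fixes with fewer than five satellites are discarded (`filter_fixes()`,
inclusive threshold). Each dive is anchored at its **temporal midpoint** —
the source text does not say start vs midpoint; the midpoint minimizes the
worst-case displacement over the dive — and longitude/latitude are
interpolated linearly in time between the bracketing fixes. Linear
interpolation on raw lon/lat is adequate at the ~km scale of 30-minute gaps
in the 52°N study region; great-circle (haversine) distances are used
wherever distance is meant. Dives outside a seal's fix envelope are dropped
and counted, never extrapolated.

The extra positional uncertainty of interpolation is summarized by

$$e = \frac{s_{\max}\,\bar t - \bar d}{\bar n}, \qquad
  \bar n = \frac{\bar t}{\overline{dur}_{dive} + \overline{dur}_{surf}}$$

potential travel distance in a mean gap, minus distance actually covered,
spread over the dive cycles in the gap. The published form of this bound was
typeset as an image and is not recoverable from the text, so this literal
operationalization of its verbal description is isolated in
`interpolation_error()` as a single point of change; $\bar n < 1$ is clamped
to 1 with a warning, keeping $e \ge 0$. $s_{\max}$ is computed per seal (a
pooled value is reported alongside, since the text does not say which).

## Habitat annotation

Rasters are plain ESRI ASCII grids; depth is stored positive-down
(GEBCO-style elevation exports are negated on read with `negate = TRUE`).
Point lookup is **containing-cell** with half-open cell rectangles
$[x, x+c) \times [y, y+c)$: categorical sediment cannot be interpolated, and
using the same rule for depth keeps the two layers co-registered; a point on
a shared edge belongs to exactly one (higher-index) cell. Detailed sediment
labels pool to fine (mud/sand), coarse (gravel/mixed), rock (rock/till), else
"unclassified"; the mapping is total. Sediment is extracted at the
interpolated dive position (the alternative — nearest fix — is not what the
located-dive table represents).

Day/night uses the NOAA solar-calculator equations with the standard
sunrise/sunset zenith of 90.833° (refraction + solar radius), all in UTC —
"local" is astronomical, from the longitude, never a civil time zone. A
timestamp is *day* iff the solar zenith is below 90.833°, which is exactly
"between local sunrise and sunset" without date bookkeeping and degrades
correctly to polar day/night. One numerical choice deserves a note: the
package first used the popular fractional-year Fourier fits for equation of
time and declination, but validation against an independent ephemeris oracle
showed systematic drift up to ~3 minutes near the equinoxes at the 2009
epoch (declination error ≈ 0.45°). The Julian-century forms used by the NOAA
spreadsheet replace them; agreement with the oracle is within seconds
year-round, comfortably inside the ±2-minute acceptance band.

## Transition matrices

For each seal, consecutive classified dives form pairs $(s_i, s_{i+1})$ over
either dive type or sediment class; `joint_transition_matrix()` normalizes
pair counts by the total pair count, so the **matrix sums to 1 over all
cells** — a joint pair-frequency table, the convention under which published
state tables of this kind sum to ≈ 1 overall. The row-conditional kernel
(rows sum to 1) is returned alongside and is what simulation-recovery tests
use, because for a chain at stationarity the joint factorizes as
$\pi_i Q_{ij}$. Design points:

- "Unclassified" sediment is a **retained state**, so a fine→rock pair
  interrupted by unmapped seabed is recorded as fine→unclassified,
  unclassified→rock — never as a spurious direct transition.
- Pairs never cross seals; aggregation (`aggregate_across_seals()`) averages
  per-seal matrices with **equal weight per animal**, the repeated-measures
  safeguard. Spread is the sample SD by default (`dispersion = "var"` and
  `sample = FALSE` switches exist because the source is inconsistent between
  "variance" in text and "standard deviation" in table captions).
- No time-gap censoring between pairs (none is stated in the source), and
  matrices are built unsplit by default with a `by_diel` stratification flag.
- Dives are not reordered silently: an unsorted table is an error.

## Pelagic-frequency model

`pelagic_frequency_table()` computes, per seal × sediment × diel cell, the
proportion of pelagic dives, over mapped sediment only. Whether shallow
dives belong in the denominator is genuinely ambiguous in the source ("out
of all dives" vs a distinction defined only for deep dives); both are
implemented — `denominator = "all"` (default) and `"deep"`
(pelagic + benthic only, the one parameter-recovery tests use, since the
generator's probabilities are conditional on deep water). The model is plain
OLS, `freq ~ sediment + diel + seal_id`, with **sequential (type-I) ANOVA**;
proportions are not transformed (the source used none). The source's printed
numerator dfs cannot be reconciled with its factor structure and are not a
target. A constant response reports $R^2 = 0$ and $F = 0$ rather than 0/0.
Cell means carry across-seal standard errors, the error-bar convention of
the source figure.

## What the simulator emulates — and what it does not

`simulate_seal()` is an event-driven correlated random walk: per dive cycle
the heading gets a Gaussian increment (`turn_sd_rad`, 0 = straight line), the
animal moves at constant `swim_speed_mps` (default 0.8 m s⁻¹, well below the
2 m s⁻¹ `max_speed_mps` bound used in the error equation), surfaces for an
exponential interval (mean 90 s), then dives for a shifted-exponential
duration (8 s floor + exponential, mean 180 s — the detection-floor
convention means no simulated dive violates the 1.5 m/8 s dive definition).
Fix attempts run on the fixed 30-minute schedule and succeed only at the
surface with probability `p_fix_success` (0.9), getting isotropic Gaussian
position noise (`gps_noise_m` = 12 m, the reported mean residual error of
this tag type) and a satellite count uniform on 4–10 so the ≥ 5 filter bites.
Dive types are drawn from local habitat: water < 50 m gives a "shallow"
truth label with dive depth ≤ the local bottom (mirroring the classifier's
own refusal to assign pelagic/benthic there); deeper water draws pelagic
with probability `p_pelagic[sediment, diel]` (depth uniform in 10–90% of the
column) else benthic (95–100%). The default `p_pelagic` encodes the target
field pattern — fine 0.36/0.52, coarse 0.28/0.39, rock 0.20/0.39 (day/night),
unclassified set to the overall day/night means 0.28/0.43 since the source
reports none for unmapped seabed.

`generate_habitat()` builds a smooth 0→350 m offshore gradient with bounded
sinusoidal relief and a nearest-seed (Voronoi) sediment mosaic over the four
codes — contiguous patches at realistic scale, shared geometry with the
depth grid.

A green recovery test therefore establishes that the pipeline's statistical
machinery is faithful — not that real seals behave like the generator. The
simulator has no haul-out phenology, tides, currents, energetics, GSM
dropout, or midwater prey structure; movement is piecewise-linear per dive
cycle; behavioural probabilities are constant in time within a diel state.
One emergent artefact is worth knowing: over a depth *gradient*, positional
error maps bottom-reaching dives onto deeper charted cells, deflating their
proximity ratio and inflating apparent pelagic frequency — visible in the
README example and precisely the error mode the 50-m gate and the ratio
diagnostic exist to expose.

## Numerical and degenerate-input conventions

- All randomness flows from one seed (`rng_seed` / `--seed`); a fixed seed
  reproduces every artifact byte-for-byte.
- Duplicate fix timestamps collapse to the more-satellite fix; ties keep the
  first.
- Seals with < 2 retained fixes lose their dives with a warning; all drops
  are counted and logged, and stage logs satisfy in = out + dropped.
- Missing/zero charted depth gives an `NA` ratio and an unclassifiable dive,
  counted, never guessed.
- Aggregation over seals with differing state sets takes the union with
  zero fill.
- Timestamps are ISO-8601 UTC end to end; readers reject unparseable rows
  with their row number.

## Known limitations

- The interpolation-error bound is an operationalization of a verbal
  description; its exact published form is unrecoverable and the function is
  a single point of change.
- Straight-line interpolation, not a state-space movement model — faithful
  to the source method, not an upgrade of it.
- No tidal correction of charted depth (named as an error source by the
  source, uncorrected there too).
- The linear model is fixed-effects OLS on proportions; a GLMM would be the
  modern choice but is out of scope by design.
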