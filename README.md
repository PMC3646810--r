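# divehab

Habitat-mediated dive behaviour from biologging data: classify seal dives as
**shallow**, **pelagic** or **benthic** from time-depth records and charted
bathymetry, link them to seabed sediment and the day/night cycle, and
summarize behavioural sequencing with per-individual Markov transition
matrices and a linear model of pelagic-dive frequency.

## The problem

Demersal predators such as grey seals (*Halichoerus grypus*) carry
Fastloc-GPS/time-depth tags that yield two asynchronous streams: sparse
surface position fixes (attempted every 30 min, successful only at the
surface) and a dive table (start/end time, maximum depth, duration). Whether
a dive went to the seabed or ended midwater cannot be read from depth alone —
it needs the charted water depth *at the dive's location*. The pipeline:

1. **Quality filter** — keep fixes computed from ≥ 5 satellites.
2. **Locate** — straight-line interpolation of each dive's temporal midpoint
   between bracketing fixes, plus an error bound
   `e = (s·t̄ − d̄)/n̄`, where `t̄`, `d̄` are mean inter-fix gap and
   distance, `s` the maximum inter-fix swim speed and `n̄` the mean number of
   dive cycles per gap.
3. **Annotate** — charted depth and pooled sediment class
   (fine = mud/sand, coarse = gravel/mixed, rock = rock/till, else
   unclassified) from ESRI ASCII grids; day/night from NOAA solar geometry
   (sunrise/sunset zenith 90.833°).
4. **Classify** — charted depth < 50 m ⇒ *shallow* (proximity ratios are
   unreliable there); otherwise the proximity ratio
   `r = max dive depth / charted depth` decides: `r < 0.95` ⇒ *pelagic*,
   `r ≥ 0.95` (including r > 1, charted-depth error) ⇒ *benthic*.
5. **Transitions** — per-seal joint frequency matrices over consecutive-dive
   state pairs (dive type; sediment class, with "unclassified" retained as a
   state), averaged across seals with each animal weighted equally.
6. **Summaries** — pelagic-dive frequency per seal × sediment × diel cell and
   a sequential-ANOVA linear model `freq ~ sediment + diel + individual`.

Because the original tag data were never deposited, the package ships an
agent-based simulator (`generate_habitat()`, `simulate_dataset()`) producing
synthetic bathymetry/sediment rasters and seal tracks with *known*
behavioural probabilities, so every stage is validated by parameter recovery.

## Worked example

```r
library(divehab)
hab <- generate_habitat(seed = 1)                      # depth + sediment rasters
cfg <- sim_config(n_seals = 4, deployment_days = 4, rng_seed = 7)
sim <- simulate_dataset(cfg, hab$depth, hab$sediment)  # 249 fixes, 4979 dives

fx  <- filter_fixes(sim$fixes)                         # >= 5 satellites
loc <- interpolate_dive_locations(fx, sim$dives)
interpolation_error(fx, sim$dives)$pooled$error_m      # +/- 86 m
cls <- classify_dives(annotate_dives(loc, hab$depth, hab$sediment))
table(cls$dive_type)
#> benthic pelagic shallow
#>    1872    2056     862

aggregate_across_seals(transition_matrices(cls, "dive_type"))
#> Mean joint pair frequencies:
#>          to
#> from      shallow pelagic benthic
#>   shallow   0.182   0.001   0.001
#>   pelagic   0.001   0.281   0.146
#>   benthic   0.001   0.146   0.240
```

The matrix reads: 28.1% of all consecutive-dive pairs were
pelagic-then-pelagic; cross-state pairs (shallow↔deep) are rare because
habitat — hence dive type — is spatially autocorrelated. Note the symmetry
joint(pelagic→benthic) ≈ joint(benthic→pelagic), as stationarity predicts.

```r
cells <- pelagic_frequency_table(cls, denominator = "deep")
fit_frequency_model(cells)
#> Linear model of pelagic-dive frequency (R^2 = 0.717)
#>           Df   Sum Sq  Mean Sq F value   Pr(>F)
#> sediment   2 0.231227 0.115614  9.9894 0.001746
#> diel       1 0.126229 0.126229 10.9066 0.004834
#> seal_id    3 0.081313 0.027104  2.3419 0.114407
#> Residuals 15 0.173605 0.011574
```

Pelagic frequency falls with substrate complexity (fine > coarse > rock) and
rises at night — the generator's behavioural structure, recovered through the
full pipeline. Recovered frequencies sit above the generator's inputs over a
depth *gradient*: position error maps some bottom-reaching dives onto deeper
charted cells, deflating their proximity ratio below 0.95 — the very
charted-depth artefact the shallow cutoff and the `ratio_error_diagnostic()`
are there to expose.

## Command line

```sh
Rscript -e 'library(divehab); quit(status = divehab_cli())' --args \
    simulate --out run1 --seed 7 --seals 8 --days 16
Rscript -e 'library(divehab); quit(status = divehab_cli())' --args \
    run-all --out run1 --denominator deep
```

(or use `inst/cli/divehab`). Subcommands `simulate`, `locate`, `annotate`,
`classify`, `transitions`, `summarize`, `run-all`; every stage logs records
in/out and every drop reason, and writes plain CSV/ASCII-grid artifacts into
`--out`. Real exports work too: GEBCO-style elevation grids via
`--negate-depth`, detailed sediment labels via `pool_sediment()`.

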