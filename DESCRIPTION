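Package: divehab
Title: Habitat-Mediated Dive Classification and Behavioural Transitions for Biologged Seals
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline from raw GPS surface fixes and time-depth dive
    records to habitat-linked dive behaviour: quality filtering of Fastloc-style
    GPS fixes, straight-line interpolation of a position for every dive,
    annotation with charted bathymetry, pooled seabed-sediment class and a
    solar day/night flag, classification of dives as shallow, pelagic or
    benthic from the dive-depth to charted-depth proximity ratio, per-individual
    Markov transition matrices over consecutive dives, and a linear model of
    pelagic-dive frequency against sediment type and time of day. Includes an
    agent-based simulator of seal tracks and dives over synthetic bathymetry
    and sediment rasters so that every stage is testable without tag data, and
    a command-line interface that chains the stages end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
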