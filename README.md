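# coastnet

Movement networks and migration phenology from coastal acoustic
telemetry.

`coastnet` is an R package for analysing passive acoustic telemetry of
coastal fish — gilthead seabream (*Sparus aurata*) being the motivating
system — tracked across a receiver network that spans estuarine lagoons
and the open sea along a longitudinal coastal gradient. Seabream follow
a two-phase annual cycle: a summer foraging phase with localized
movement in lagoons, and an autumn–winter spawning phase with
long-range, predominantly eastward migration to offshore aggregation
sites. The package turns raw detection tables into quantitative
descriptions of that cycle and is aimed at movement ecologists and
fisheries scientists working with receiver-array data.

## What it computes

Starting from three tables (detections, receiver stations, tagging
metadata), the pipeline:

1. **Filters** detections with an auditable rule set (pre-release and
   inactive-station records, exact duplicates, isolated single
   detections, implied-speed violations above 100 km/day), and screens
   for **dead fish** with three deterministic criteria (fixed-station
   detections in the September–November movement season; long-term
   confinement to few overlapping receivers; slow unidirectional
   drift).
2. Segments **residency events** under a continuous-presence rule:
   detections at one station array belong to one event while
   inter-detection gaps stay within 1.5 h (thirty times the longest
   nominal tag delay), and a valid event needs at least two detections.
   The residency index of a fish is the fraction of days at liberty
   with at least one detection.
3. Builds **directed weighted movement networks**: nodes are station
   arrays (receiver clusters at lagoon entrances are pooled), an edge
   u→v counts consecutive detections of one fish at different arrays.
   Per-fish layers feed a metric suite — mean degree, mean graph
   strength, edge count and density m/(n(n−1)), average path length,
   normalized degree and betweenness centrality maxima (betweenness
   uses inverse-weight costs), weighted traversal distance (great
   circle) — and season-pooled global layers (foraging 15 Apr–30 Sep,
   spawning 1 Oct–14 Apr) are compared by mean out-degree, mean edge
   value and modularity.
4. Detects **spatial communities** on the aggregate network with the
   Louvain algorithm at resolution 1 after a log(1+w) edge transform,
   and tabulates monthly within-community movements and the number of
   fish moving between communities in consecutive-month windows.
5. Quantifies **spawning phenology**: per lagoon and year, the peak
   7-day bin (anchored 1 September) of last home-lagoon detections;
   first arrivals at spawning-flagged arrays per season; daily presence
   counts and multi-year return fidelity.
6. Models **size effects** with GAMs: each log-transformed network
   metric is regressed on a penalized spline of fork length plus an
   origin (lagoon/sea) contrast, with time-at-liberty class as a random
   intercept, mirroring `mgcv::gam(log y ~ s(length) + origin +
   s(liberty_class, bs = "re"))` with basis-dimension checking.

Because the corresponding field data are not bundled, the package
includes a first-class **synthetic telemetry generator**
(`simulate_cohort()`): an agent-based model of the two-phase cycle on a
1-D coastal axis with lagoons as monitored appendages, size-dependent
migration, seeded deaths with realistic post-mortem detection patterns,
and logged ground truth (true dwell intervals, departures, deaths) that
the test suite uses as oracles.

## Worked example

```r
library(coastnet)

cfg <- sim_config(n_fish = 30, rng_seed = 7)   # 3-year study conditions
run <- run_pipeline(cfg, fit_models = FALSE)
run
#> <coastnet_run> 30 fish (26 retained), 139971 detections after filtering, 90 arrays
#>   communities: 12 (Q = 0.558); residency events: 16008

run$global_layers$comparison[, c("period", "mean_out_degree",
                                 "mean_edge_value", "modularity")]
#> # A tibble: 2 × 4
#>   period   mean_out_degree mean_edge_value modularity
#>   <chr>              <dbl>           <dbl>      <dbl>
#> 1 spawning            8.23            11.3      0.491
#> 2 foraging            3.82            11.1      0.744

head(run$emigration$peaks, 3)
#> # A tibble: 3 × 5
#>   lagoon  year peak_bin bin_start  n_fish
#>   <chr>  <int>    <int> <date>      <int>
#> 1 Berre   2019        3 2019-09-22      4
#> 2 Berre   2020        3 2020-09-22      3
#> 3 Berre   2021        3 2021-09-22      2
```

Reading the output: of 30 simulated fish, 26 survive the quality filter
and dead-fish screen. The spawning-season global layer has a higher
mean out-degree than the foraging layer (8.2 vs 3.8 unique departures
per node) and lower modularity (0.49 vs 0.74) — spawning movement is
more extensive and less compartmentalized, the seasonal contrast the
seasonal layers exist to expose. Berre Lagoon's peak emigration bin
(22–28 September) precedes the other lagoons' mid-October peaks in
every year, matching the generator's configured departure schedule.

The pipeline can also be driven from a YAML configuration with
`run_all("cfg.yaml", out_dir = "run1")`, which writes every stage's
tables plus a manifest of file digests; identical configuration and
seed reproduce identical digests.

## Package layout

- `R/sim_config.R`, `R/simulate.R` — generator configuration and the
  agent-based simulator.
- `R/ingest.R` — loading, filter rules with audit, dead-fish screen,
  array pooling, liberty classes.
- `R/residency.R`, `R/movenet.R` — residency segmentation, layers and
  metric suite.
- `R/community.R`, `R/phenology.R`, `R/size_effects.R` — Louvain
  communities and flows, emigration/arrival/presence, GAMs.
- `R/pipeline.R` — orchestration, YAML configs, manifests.
- `vignettes/coastnet-methods.Rmd` — the methods vignette (model,
  assumptions, parameter choices, limitations).
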