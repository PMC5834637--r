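# pengcensus

Estimating the abundance of colonially nesting seabirds — Adélie penguins
(*Pygoscelis adeliae*) in the Danger Islands archipelago are the motivating
case — from a multi-modal survey: direct ground counts, automated counts of
UAV orthomosaics, and multispectral satellite imagery for colony-area change.
The package is aimed at quantitative ecologists who need the full chain from
raw detections to an archipelago-wide abundance estimate with defensible
uncertainty, and at methods developers who want a tested, seeded simulation
bench for each stage.

## What it implements

**Ground protocol.** Each counting unit is counted three times; the counts
must agree within 5% of their mean, otherwise the unit is subdivided and
recounted (`assess_agreement()`, `protocol_count()`). Counts carry the
standard N-level precision classes — N1 (≤5%), N2 (±10%), N4 (±50%) —
assigned by `classify_precision()`.

**Automated counting of UAV imagery.** Orthomosaics are split into 512 × 512
tiles (`tile_raster()`) and candidate nests detected by a scale-matched
difference-of-Gaussians blob detector (`detect_candidates()`,
`detect_island()`). Detections `D` are thinned by a nearest-neighbour
spatial filter: a point is retained iff at least *m* other detections lie
within radius *r*,

    retain(p)  ⇔  #{ q ∈ D \ {p} : ‖p − q‖ ≤ r } ≥ m,

with *r* chosen from the NN-distance distribution (`fit_filter_rule()`,
`apply_filter()`). Nesting penguins attract each other (short NN distances);
rock/shadow false positives are close to complete spatial randomness (long
NN distances), so the two components of the NN-distance mixture separate and
isolated false positives are rejected.

**Calibration and census.** Filtered counts are calibrated per site against
manually counted validation plots by simple linear regression
(`fit_calibration()`, `apply_calibration()`), per-island counts summed
(`sum_census()`), and class half-widths propagated to a 95% confidence
interval on the archipelago total by Monte Carlo (`propagate_error()`), with
the regional share computed against the published CCAMLR subarea 48.1
baseline (`regional_share()`).

**Remote sensing.** Scenes from different sensors are cross-calibrated by
per-band mean differences (`estimate_offsets()`, `apply_offsets()`),
classified into guano/non-guano (`classify_guano()`), reduced to a common
30 m grid (`reduce_to_grid()`), and compared across epochs
(`compare_epochs()`).

**Simulation bench.** Every input can be generated with seeded
reproducibility: clustered hard-core colony layouts
(`generate_colony_layout()`), orthomosaic-like rasters with confusable
artifacts (`render_orthomosaic()`), observer counts
(`simulate_observer_count()`), and paired multispectral scenes
(`generate_scene_pair()`). `run_pipeline()` orchestrates everything from a
single YAML/R config, and `exec/pengcensus` is a thin command-line front end.

## Worked example

```r
library(pengcensus)

## aggregate the packaged per-island census table
sites <- danger_islands_counts()
total <- sum_census(sites, "adeliae")
est <- propagate_error(sites[sites$species == "adeliae", ],
                       interpretation = "normal95", n_reps = 1e5, seed = 7)
est
#> census_estimate: 751,527 nests (95% CI [709,138, 793,886]; normal95, 100000 reps)
regional_share(total)$percent_rounded
#> [1] 55
```

The point estimate is the deterministic sum of the nine per-island Adélie
counts; the interval reflects each island's precision class (e.g. a ±10%
"N2" count contributes a truncated-normal error with 1.96 σ equal to 10% of
its count); the share says these islands hold 55% of the combined regional
population.

A simulated end-to-end survey of one island:

```r
cfg <- default_config()
cfg$islands$n <- 1
m <- run_pipeline(cfg, output_dir = tempfile())
m$islands[, c("island", "true_n", "n_detected", "n_retained", "count")]
#>   island true_n n_detected n_retained count
#> 1  sim01    584        691        596   581
```

Here 584 nests were simulated, the detector fired 691 times (nests plus
artifacts), the spatial filter kept 596 points (a few in-colony artifacts
survive, since spatial structure cannot identify them), and site
calibration corrected the count to 581 — an error of −0.5%, well within
the ±10% N2 band the automated track claims.

## Documentation

The methods vignette (`vignettes/penguin-census-methods.Rmd`) describes the
models, the parameter defaults and why they were chosen, what the simulation
does and does not emulate, and known limitations.
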