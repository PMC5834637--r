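---
title: "Methods: multi-modal censusing of penguin colonies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-modal censusing of penguin colonies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pengcensus)
```

## The estimation problem

A complete census of a remote seabird archipelago combines counting methods
of very different character: careful ground counts where landing and time
permit, automated counts of UAV orthomosaics where they do not, and
photographic counts from ship or shore for islands visited only briefly.
Each method carries its own error, summarised by the standard N-level
precision classes (N1 ≤ 5%, N2 ± 10%, N4 ± 50% of the count). The package
implements each counting track, the calibration tying the automated track to
ground truth, and the propagation of the per-island classes to an
archipelago-wide 95% confidence interval. A parallel remote-sensing track
cross-calibrates multispectral scenes across sensors so that colony (guano)
area can be compared across decades.

## Ground protocol

A counting unit (a sub-colony, or a roped subsection of one) is counted
three times; the triple is accepted iff every count lies within 5% of the
triple's mean (boundary inclusive; an all-zero triple is accepted). Failing
units are split in two and recounted. Design choices the protocol text does
not pin down, resolved here:

* **Accepted-unit estimator** — the rounded mean of the three agreeing
  counts. Under a symmetric observer error this is unbiased; no alternative
  (min, max, last count) has that property.
* **Subdivision arity** — binary, with the unit's true nests allocated
  binomially between halves in simulation.
* **Observer error** — a truncated normal on the count scale with relative
  standard deviation `cv` (default 0.03) and multiplicative bias (default
  1). Field protocols bound the *agreement* of three counts at 5%, not the
  error of a single count, so `cv` is a free simulation parameter; 3% makes
  triples agree most of the time at typical unit sizes, matching the
  observation that subdivision is the exception rather than the rule.

Because `cv` is relative, acceptance probability in this model does not
improve as units shrink; subdivision helps by giving independent retries,
not smaller relative errors. Real counts of smaller units are likely also
relatively more accurate, so simulated subdivision depths are conservative.

## Simulated colonies and imagery

The synthetic-data generator is the bench on which every downstream stage is
tested, so its defaults are the package's statement of "realistic
conditions", chosen once:

* **Spatial structure** — nests are a clustered hard-core process: parent
  (sub-colony) centres uniform over the island extent, offspring displaced
  isotropically (Gaussian, scale 3 m), proposals closer than 0.7 m to an
  accepted nest rejected (dart-throw thinning, with an explicit budget so
  infeasible packings fail loudly). Published measurements of nest spacing
  in dense Adélie colonies put centre-to-centre distances near 0.7 m, and
  sub-colonies are tens of metres across; neither number is critical, but
  together they produce the unimodal short-distance NN component the
  spatial filter relies on.
* **Island geometry** — default extent 200 × 200 m with four sub-colonies
  of ~150 nests, their centres inset from the extent edge by twice the
  cluster radius (sub-colonies sit back from the shoreline, and a
  corner-truncated cluster disk could not pack the requested nest count at
  the hard-core spacing). Real colonies sit as discrete patches on mostly bare
  ground; the colony footprint fraction (here ≈ 5%) matters because
  false positives that fall *inside* a colony are indistinguishable from
  nests by spatial structure alone and bound the achievable artifact
  rejection rate.
* **Rendering** — each nest is an isotropic Gaussian blob (σ = 0.12 m,
  amplitude 1) stamped at its world position on a 5 cm/px grid, additive
  pixel noise σ = 0.02. Artifacts ("rocks and shadows") are a homogeneous
  Poisson field (default 0.003 m⁻², roughly one artifact per eight nests in
  the default geometry) rendered *identically* to nests — the worst case
  for the detector, forcing all false-positive removal onto the spatial
  filter.
* **Coordinates** — world metres, y north; rasters row-major with the
  pixel-centre convention; the affine world↔pixel map is invertible.

What the simulation does **not** emulate: perspective and mosaicking
artefacts, lighting gradients, penguins walking between nests, mixed
species, vegetation, or terrain. Passing tests demonstrate the pipeline's
statistical machinery under the stated point-process and noise model, not
detector performance on real imagery — the detector here is deliberately a
classical stand-in (see below).

## Detection

The published workflow used a trained neural detector; its weights are not
reproducible, so the package substitutes a classical difference-of-Gaussians
blob detector behind the same contract: tiles in, scored points in world
metres out, tuned for high recall and tolerating spatially unstructured
false positives. DoG scales are σ and 1.6σ with σ matched to the rendered
blob; local maxima above an absolute response threshold (default 0.08, about
a third of the response of an isolated unit-amplitude blob) become
detections. Tiles are processed with a 16-pixel context halo and maxima
assigned to the tile that owns their pixel, which makes tiled detection
exactly equal to full-raster detection; seam duplicates are merged to their
score-weighted centroid iterated to a fixed point, so merging is idempotent.
Edge tiles keep their native size, preserving pixel content exactly.

## The nearest-neighbour filter

The retention rule is "at least *m* other detections within radius *r*",
evaluated against the original detection set in a single pass. The rule
reduces to a pure NN-distance threshold at *m* = 1; the default *m* = 2
makes chance pairs of isolated false positives insufficient for retention.
Applying the filter once is deliberate: iterating to a fixed point would
erode colony edges.

Choosing *r* is the module's central design decision. Three methods are
provided:

* **fixed** — pass *r* through (fully loggable, for audits and replays).
* **quantile** — the 90th percentile of 1-NN distances. Simple, but the
  pooled quantile sits on a knife edge: it lands correctly only when the
  false-positive fraction is close to (1 − q).
* **mixture crossover (default)** — the NN distances of the pooled
  detections form a two-component mixture: a structured colonial component
  at nest spacing and a component from the spatially random false
  positives, whose NN law is Rayleigh-like with a much larger scale. At
  realistic intensities the two are separated by a nearly empty gap. The
  crossover is located nonparametrically: kernel density of log NN
  distances, then the first local minimum after the colonial mode at which
  the density has collapsed below 5% of that mode. A parametric
  lognormal-plus-Rayleigh crossover was tried first and rejected: the
  clustered process has a heavier short-distance tail than a lognormal, so
  the parametric crossover hugged the colonial bulk and rejected ~10% of
  true nests; the density-valley form places *r* in the gap and is
  insensitive to the false-positive fraction. The NN rank used for the
  density defaults to *k* = *m*, because the rule thresholds exactly the
  *m*-th-NN distance.

Degenerate inputs (all NN distances identical, e.g. a perfect grid) fall
back to a fixed default radius with a warning; an apparent single-component
density (no spatially random points) falls back to the 90th-percentile
rule. At the default study conditions the rule rejects ≈ 95% of uniform
artifacts while losing well under 2% of nests; the retained false positives are
almost entirely those falling inside colony footprints, which spatial
structure cannot identify and which site calibration absorbs instead.

## Calibration and error budget

Automated counts are tied to truth by ordinary least squares of the manual
validation count on the automated count, per site (residual scale from the
usual n − 2 degrees of freedom, zero when n = 2, and a 95% prediction
interval giving the relative uncertainty that the N classification reads).
Validation plots are square grid cells chosen to span the range of local
detection density — fringe cells as well as dense cores — so that the
filter's small edge erosion is represented in the regression rather than
extrapolated. Defaults: 16 plots of 20 m.

Because the regression is fit at plot scale, the island estimate aggregates
per-cell predictions over every occupied cell (n·a + b·Σd) rather than
predicting once at the island total: a per-plot additive bias — retained
in-colony artifacts average a fraction of a point per cell — would
otherwise be applied once instead of once per cell, which showed up as a
systematic overestimate before the aggregation was corrected.

The manual plot counts use a 1% relative error, distinct from the 3% field
`cv`: clicking every incubating bird in a zoomed orthomosaic patch is far
more repeatable than counting hundreds of moving birds from a vantage
point. With ~10 effective plots this puts the per-island calibration error
near 0.5%, and the full chain recovers simulated island totals with a mean
absolute error of ≈ 0.3–0.4% (every island well inside the ±10% N2 band) —
the same order as the 0.6% mean difference reported for the field workflow
that motivated the design.

## Error propagation

How a "±X%" precision label maps to a distribution is not standardised.
Two interpretations are implemented and reported side by side in logs:

* **normal95 (default)** — the half-width is the 95% half-width of a
  normal error: σ = hw / 1.96, truncated at zero.
* **uniform** — the half-width of a uniform error (a *wider* resulting CI,
  since hw/√3 > hw/1.96).

Per replicate every island is drawn independently under its class and the
replicate totals' empirical 2.5/97.5 percentiles give the interval; the
point estimate stays the deterministic sum. Island errors are assumed
independent — a documented limitation: shared observers, weather or imagery
would correlate them and widen the true interval. The Monte Carlo is
converged at the default 10⁵ replicates (half-width moves < 1% on
doubling). On the packaged archipelago table the normal95 interval is
roughly symmetric with half-width ≈ 42,000 nests; the published interval for
the same table is [710,103–792,443], whose slight asymmetry suggests the
original propagation was not exactly this normal scheme, so exact endpoint
reproduction is not claimed — coverage is instead verified directly on
synthetic archipelagos with known truth (93–97% at nominal 95%).

## Remote-sensing track

Cross-calibration subtracts per-band mean differences against a reference
sensor, estimated over a comparable-pixel mask (default: all pixels;
cloud/sea masking is out of scope). "Similar bands" across sensors are an
explicit name mapping supplied in config. The guano classifier is a
pluggable slot whose default is a two-class minimum-distance discriminant on
reflectance vectors (LDA with equal priors and isotropic covariance);
published retrieval algorithms can be plugged in unchanged. Fine masks and
polygons are reduced to the 30 m analysis grid by majority coverage
(threshold 0.5, configurable), which conserves area to within a one-cell
boundary ring and is the identity on inputs already on the grid. Epoch
comparison reports per-epoch areas, consecutive ratios and cellwise
gained/lost/stable counts.

## Reproducibility and problem sizes

Every generator takes an explicit seed and restores the caller's RNG state;
a pipeline run fans one master seed into per-stage substreams (a small
string hash of seed and stage label), so stages can be re-run independently
and a fixed config reproduces its census summary byte-for-byte. The test
suite and the acceptance script use scaled-down problem sizes chosen as the
package's own test conditions: islands of ~600 nests (renders of
4000 × 4000 px at 5 cm/px), 400 synthetic archipelagos for coverage checks,
10⁵ Monte Carlo replicates for the census interval, 64 × 64-cell scenes for
the remote-sensing checks.

## Known limitations

* The stand-in detector shares only the *contract* of a trained neural
  detector; its recall/precision on real imagery is untested and untestable
  here.
* Spatially structured false positives (e.g. shadow lines along colony
  edges, walking birds inside colonies) defeat a purely spatial filter by
  construction; calibration absorbs their average effect but not their
  variance.
* Independence assumptions: across islands in the propagation, and between
  plots in calibration.
* The triple-count model's relative `cv` does not shrink with unit size, so
  simulated subdivision behaviour is pessimistic for small units.
* Georeferencing is an idealised affine world↔pixel map; no orthomosaic
  distortion model.
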