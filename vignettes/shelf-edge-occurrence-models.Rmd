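---
title: "Modelling shelf-edge grouper occurrence and scoring marine reserves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling shelf-edge grouper occurrence and scoring marine reserves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefsdm)
```

## The problem

Speckled hind and warsaw grouper are large, long-lived reef fishes of the
southeastern U.S. shelf edge. They are rarely encountered: even pooling
decades of trap, hook-and-line, ROV, diver and logbook records, only 2-7%
of sampling events detect one. Both species are tied to hardbottom
(rocky/reef) seafloor in the 25-100 fathom (45.7-182.9 m) band, and both
suffer near-total release mortality from barotrauma, which makes spatial
closures — marine protected areas where the fish are — the main viable
management lever. The package implements two complementary ways of mapping
where the fish are, and the accounting needed to score closures against
those maps.

## The rule-based habitat classification

The spatial unit is a one-arcminute grid cell carrying a representative
depth (assigned to 5-fathom bins) and a habitat code from bottom-mapping
data: `HB` (any hardbottom datum in the cell), `NH` (data present, all
not-hardbottom), `UN` (unsampled). Unsampled cells with maximum percent
slope strictly greater than 1.45 — the mean maximum slope of mapped
hardbottom cells, taken here as a configuration constant — are promoted to
`PH` (possible hardbottom), since steep relief at the shelf edge is a
strong hardbottom proxy.

Each cell is then classified for a species, in strict precedence:

1. **Known** — detected by any source other than the headboat logbook;
2. **Probable** — a headboat detection in the cell, or habitat `HB`/`PH`;
3. **Not suitable** — habitat `NH`, more than 5 samples, no detection of
   any kind;
4. **Unknown** — otherwise.

Headboat positions are self-reported on a coarse (1/6 degree) grid and are
not trusted to pin a cell down, so a headboat-only detection earns only
*Probable*. Any detection blocks *Not suitable*. Two boundary decisions
were genuinely open and are resolved as follows: exactly 5 negative
samples on `NH` habitat falls through to *Unknown* (the package never
declares habitat unsuitable below the stated evidence threshold), and
"samples" counts only effort-bearing sources — headboat trips without a
detection are not counted, because the headboat series carries no reliable
per-cell effort.

Cell areas are computed on a sphere (radius 6371.0088 km) rather than in a
projected CRS. At study latitudes the discrepancy is far below 1%, and
every reported metric is a ratio of such areas, so the systematic part
cancels. The depth-band filter is closed, `[25, 100]` fathoms; depth bins
are half-open `[k*w, (k+1)*w)`; a cell is assigned once, by its
representative (centroid) depth, rather than duplicated across bins it
straddles.

## The logistic occurrence model

The probability that a sampling event detects the species is modelled with
a logit link:

```
logit P(detect) = gear effect + f(latitude) + g(depth) [+ habitat]
```

The observation unit is one sampling event with a binary response —
multiple captures per event are rare, and catchability differs so much
among gears that counts are not comparable. The gear factor absorbs
catchability; `DW-ROV` is the reference level, and prediction surfaces fix
the gear effect at a standardization gear (default `DW-ROV`) so maps are
comparable across sampling methods.

Latitude enters as one of: nothing, a continuous degree term, a centered
squared term, or 1-degree categorical bins. Depth: nothing, 10-fathom
bins, 5-fathom bins, or a centered squared term. Habitat (`HB` reference,
`PH` mapped to `HB`) is in or out. All combinations give the 32-candidate
set of `candidate_specs()`. Squared forms are single columns without the
linear term, mirroring how such dome-shaped effects are usually reported
for these stocks; they are centered at the domain midpoints (30 degrees N,
62.5 fm) to reduce collinearity with the intercept — centering changes the
intercept's meaning but not fits, AIC, or predictions. Fitting is by IRLS
(relative deviance tolerance 1e-8, at most 100 iterations) with standard
errors from the Fisher information. Complete separation — a perfect fit,
residual deviance below 1e-6 — is an error, not a result; quasi-separated
factor cells (a bin with no detections) keep their point estimates and
predictions but get `NA` standard errors.

Deviance explained is decomposed sequentially: the component for a
variable group is the drop in residual deviance when that group enters,
as a percent of the null deviance, under the default entry order gear,
latitude, depth, habitat. Components depend on the order; their sum — the
total percent of null deviance explained — does not, and the package
checks that identity to 1e-8.

The model is interpreted only inside its domain: 25-100 fathoms, and
latitude 26-34 degrees N for speckled hind, 28-34 degrees N for warsaw
grouper (positive warsaw records south of 28 degrees are so scarce that
no model can be supported there). Predictions outside the domain raise an
error rather than silently extrapolating.

## Model selection

Two criteria are computed and deliberately kept apart, because they need
not agree:

* **AIC**, `2k - 2 logLik`, over all candidates;
* **repeated k-fold cross-validation** (default 10-fold, 10
  re-randomizations; 5-fold supported). Per fold, the candidate is fit to
  the training set, a classification threshold is chosen on the
  *training-set* ROC at the point maximizing sensitivity plus specificity
  (ties to the smallest threshold, which favors sensitivity for rare
  positives), and the held-out false-positive and false-negative rates
  are recorded. Rates are aggregated as mean and SD over all
  fold-by-repeat evaluations; the SD is wide on 2-7% occurrence data,
  which is exactly why the re-randomization is repeated.

ROC thresholds are midpoints between consecutive sorted unique scores,
with infinite sentinels, under "predict positive iff score >= threshold";
this makes the argmax well-defined and checkable against brute-force
enumeration. Unstratified splits on sparse data occasionally produce a
training fold with no positives; such partitions are re-randomized under
a derived seed (after 10 failures the error advises stratified folds). A
test fold contributes its FPR whenever it has negatives and its FNR
whenever it has positives, so degenerate folds aggregate rather than
abort. The best-by-CV model minimizes mean FPR + FNR (ties to lower AIC);
the best-by-AIC model minimizes AIC; downstream reports carry both as an
inter-model uncertainty range.

## Reserve protection accounting

For a reserve polygon, three metrics are computed over the analysis band:

* **percent of habitat class** — class area inside the reserve over the
  jurisdiction-wide class area, for *Known* and for *Known & Probable*;
* **percent of stock** — area-weighted detection probability inside over
  the jurisdiction-wide total, times the reserve's efficiency weight
  (1 for no-take, 0.5 for no-anchoring CHAPC-type protection). The ratio
  form makes the metric invariant to uniform rescaling of probabilities,
  so it reads as a percent of relative abundance;
* **protection per unit area** — percent of stock per square kilometre.

Cell-reserve overlap is an exact polygon-rectangle intersection
(Sutherland-Hodgman clipping in a local equal-area frame, longitudes
scaled by the cosine of cell latitude, in cell-local coordinates to avoid
floating-point cancellation). Aggregates over several reserves are
resolved per cell: the protected fraction is `min(1, sum of overlaps)`
and the efficiency is the maximum among covering reserves, so overlapping
reserves never double-count. Note the cap is a cell-level convention, not
a geometric union: two reserves each covering the same 60% of one cell
count that cell as fully protected. At one-arcminute resolution against
reserves tens of kilometres across, the distinction is negligible; it
vanishes entirely for cell-aligned geometry. A metric whose
jurisdiction-wide denominator is empty (no *Known* cells, or a reserve
wholly outside a species' modelled domain) is reported as not evaluable
(`NA`), never as a silent zero.

## What the synthetic generator emulates

The package's tests run on synthetic data because the underlying fishery
datasets are proprietary and undeposited. The generator reproduces the
statistical structure the analyses depend on:

* a one-arcminute shelf strip (default 240 x 60 cells, 4 x 1 degrees)
  whose depth increases offshore at 120 fm/degree with 3 fm noise, so the
  25-100 fm band occupies the middle of the strip;
* hardbottom laid down by a seeded Markov neighbour rule (seeding
  probability 0.05, eight-fold continuation next to existing hardbottom),
  giving the patchy, along-shelf-clustered reef tracts visible in mapped
  data; 40% of cells are unmapped, and exponential slope draws (means 2.5
  vs 0.8 by bottom type) let the slope rule recover part of them as `PH`;
* gear-stratified effort: 70% headboat, with per-gear depth preference
  windows (traps shallow, ROVs deep) emulating the strong shallow bias of
  fishing effort;
* detections from the same logit model the package fits. True effect
  magnitudes follow the values estimated for these stocks where such
  values are printed (latitude 0.59 per degree N; gear offsets from -2.64
  to +2.36 with `DW-ROV` at 0); the squared-depth coefficient, reported
  only as 0.00 at two decimals but strongly significant, is set to
  -0.0015 per fm^2 (about -2 logits across the half-band), and habitat
  effects are NH -1.2, UN -0.6, a realistic hardbottom affinity. The
  intercept is never hand-picked: it is calibrated by bisection so the
  expected detection rate hits 4.5%, the midpoint of the 2-7% occurrence
  window, and the calibrated ground truth is exported for recovery tests.

What the generator does *not* emulate: spatial autocorrelation of
detections beyond what the covariates induce, positional error (headboat
grid-snapping), effort-less presence records, and vintage effects in
museum records. Passing recovery tests therefore show the estimator and
selection machinery are correct under the model's own assumptions, not
that the real data meet those assumptions.

## Numerical and design choices

* IRLS tolerance 1e-8 (relative deviance change), 100 iterations max.
* Intercept calibration: bisection on the expected rate, 60 iterations on
  [-60, 20] logits; unattainable targets are an error with diagnostics.
* Folds: sizes differ by at most 1; stratified folds balance positives to
  within 1; all partitions are seeded and reproducible, with child seeds
  derived by a fixed integer recurrence so distinct stages never share a
  stream.
* Ties in threshold selection go to the smallest qualifying threshold;
  ties in CV selection go to the lower-AIC candidate.
* Unseen factor bins at prediction time (a test-fold latitude bin absent
  from a training fold) fall to the reference level rather than erroring;
  this is the standard pragmatic choice for dummy-coded CV.
* Reserves are validated (>= 3 vertices, no self-intersection, efficiency
  in [0, 1]); multi-ring reserves assume disjoint rings.

## Problem sizes used in the test-suite

Statistical checks in the suite use sizes chosen to make the properties
they test sharp: Wald-interval coverage uses 100 replicates of 20,000
events; AIC-selection frequency uses 50 replicates of 10,000 events
against all 32 candidates; the end-to-end pipeline test runs a 2-degree
strip with 2,500 events, an 8-candidate subset and 5-fold CV repeated
twice. Unit tests run on a 120 x 40 cell strip with 4,000 events.

## Known limitations

* Detection probability only: no abundance, occupancy, or hierarchical
  detection/occupancy modelling, and no spatial autocorrelation terms.
* The equal-area approximation and spherical cell areas are adequate at
  one-arcminute scale and mid latitudes; a polar or basin-scale
  application would need a projection engine.
* The cell-level `min(1, sum)` union convention slightly overstates
  protection where reserves partially overlap *within* a single cell.
* Model selection searches the fixed 32-candidate set; it does not
  penalize, regularize, or average models.
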