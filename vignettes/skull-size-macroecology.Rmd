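---
title: "Skull-size macroecology from landmarks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skull-size macroecology from landmarks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyenamorph)
```

`hyenamorph` implements a complete chain for studying geographic variation
in skull size from 2D landmark photographs: centroid-size extraction via
generalized Procrustes analysis (GPA) with bending-energy sliding of
semilandmarks, interpolation of census population densities by universal
kriging under a stable semivariogram, Jenks natural-breaks classification,
trend-surface regression with AIC subset selection, and sexual
size-dimorphism summaries by region. This vignette explains the models,
the tunable parameters, and the design choices where the methodology left
them open.

## Size from landmarks

Each specimen view (ventral cranium, lateral cranium, lateral mandible)
is a configuration of 2D points digitized on a photograph carrying a
10-mm scale bar. Coordinates stay in image units inside the package; the
scale factor is stored separately and applied exactly once, when centroid
size

$$\mathrm{CS} = s \sqrt{\sum_i \lVert p_i - \bar p \rVert^2}$$

is computed. This "apply-once" rule removes a classic double-scaling
hazard when TPS files are round-tripped between tools.

`gpa_align()` is classical generalized least-squares Procrustes
superimposition: center, scale to unit centroid size, rotate each
configuration onto the running consensus, re-estimate the consensus, and
iterate until the consensus RMS change falls below `tol` (default
`1e-8`). Two choices deserve note:

* **Rotations only.** The 2D orthogonal Procrustes step is solved in
  closed form as a proper rotation (determinant +1). Skull photographs
  have fixed chirality, so reflections are never legitimate.
* **Arbitrary global orientation.** As in other GPA implementations, the
  consensus orientation is set by the initialization (the first
  specimen); all reported quantities (centroid sizes, Procrustes
  distances, bending energies) are invariant to it.

Physical centroid sizes are recorded *before* unit-size normalization and
are taken from the digitized configurations (sliding, below, operates in
shape space and does not revise them).

## Sliding semilandmarks

Semilandmarks along outlines carry a nuisance parameter — their position
along the curve. `slide_semilandmarks()` removes it by minimizing
thin-plate-spline bending energy against the consensus. The bending
energy matrix is the standard 2D construction with kernel
$U(r) = r^2 \log r^2$, bordered by the affine block; its quadratic form
annihilates affine deformations exactly (a property the test suite
asserts at `1e-10`).

Per pass, each semilandmark may move only along its local tangent — the
chord between its `before` and `after` neighbors in that specimen,
recomputed every pass. The displacement magnitudes solve a small
generalized-least-squares system exactly, so energy cannot increase
within a pass; after every pass the superimposition is re-run and the
consensus (hence the bending-energy reference) updated. Iteration stops
when the relative change in total energy drops below `tol` (default
`1e-6`) or after `max_iter` passes; the full energy trace is returned so
the monotone-decrease property is observable rather than assumed.

## The density surface

Census density estimates are sparse, so the pipeline interpolates them by
universal kriging (`universal_krige()`): best linear unbiased prediction
with a monomial drift (default order 1), weights from a stable
semivariogram

$$\gamma(h) = \mathrm{nugget} + \mathrm{psill}\,
  \bigl(1 - e^{-(h/\mathrm{range})^s}\bigr).$$

`variogram_model()` defaults to the fit published for this surface:
nugget 0.439, partial sill 0.2855, range 1.928, interpreted in degrees —
the only units in which a range of 1.928 is plausible for a continental
surface. Because GIS packages disagree about whether a printed "sill" is
partial or total, both readings are supported (`sill_is_total`). The
shape exponent is not published; the default is 1.5, halfway between the
exponential and Gaussian limits, and is configurable and logged. Drift
order (0–2) and the 12-lag empirical variogram width are likewise
configuration with logged defaults. Kriging distances are Euclidean in
degree space to match the range units; great-circle kilometres
(`great_circle_km()`, haversine on a 6371-km sphere) are used only for
nearest-neighbour reporting and outlier exclusion.

Numerical conventions: $\gamma(0) = 0$ (so coincident queries reproduce
their sample); duplicate sample locations are averaged with a warning
(they would make the system singular); negative predictions of a
physically positive variable are clipped to the smallest positive sample
value, with a warning and a count on the result (`clip_negative = FALSE`
turns this off, e.g. when kriging log density, which the synthetic
pipeline does because simulated densities are log-normal).

Interpolated densities at specimen localities are classified by
`categorize_density()`: Fisher–Jenks optimal 1-D classification
(`jenks_breaks()`, exact dynamic programming, deterministic) with k = 4,
then the top three classes merged into `high` — the reduction used when
only the lowest-density class relates to size. `size_classes()` applies
the same Jenks machinery with k = 3 for the small/medium/large map
tables.

## Size models

The spatial component of centroid size is a trend surface in longitude
(X) and latitude (Y). The candidate set is every monomial $X^iY^j$ with
per-coordinate degree $i, j \le 4$ (24 terms): published models of this
kind retain terms such as $X^3Y^4$, which only a per-coordinate reading
of "fourth-order" admits. Coordinates are centered before powering to
tame the conditioning of the monomial basis; coefficients are therefore
reported in the centered basis, with the centering constants attached to
the design.

`select_spatial_model()` minimizes Gaussian AIC (error variance counted
as a parameter, the `stats::AIC` convention) over subsets, with no
marginality constraint — interactions may survive without their parents,
as the published models do. Up to `exhaustive_limit` (default 15)
candidates, every subset is enumerated; beyond that, bidirectional
stepwise searches from the null and global models run and the better
endpoint is taken, with the strategy recorded. Ties break toward fewer
terms, then lexicographically, making selection fully deterministic.

The combined model adds sex (reference female; unknown-sex specimens are
their own level), annual mean temperature, annual precipitation, density
class (reference low) and collapsed land cover (reference forest) to the
selected spatial terms. `vif()` screens for collinearity (generalized VIF
with the $\mathrm{GVIF}^{1/2\mathrm{df}}$ adjustment for factor terms),
and `backward_stepwise_aic()` then drops spatial terms — only spatial
terms; the biological and environmental covariates are protected — one at
a time while AIC improves. Diagnostics on the reduced model are
Shapiro–Wilk (delegated to `stats`), the Durbin–Watson statistic, Cook's
distances, and the residual ACF with $\pm 1.96/\sqrt{n}$ bounds. p-values
are two-sided from the t distribution with residual df, uncorrected for
multiplicity, matching the source analysis's reporting.

## Regions and dimorphism

The published regional boundaries (the Nile and the East African lake
system) are verbal, not machine-readable. `region_scheme()` therefore
ships deterministic half-plane rules — southern below 12°S, then
eastern/western split at 29°E — plus a per-country override table, all
user-replaceable; determinism was preferred over cartographic fidelity.
Specimens whose nearest neighbour is farther than 2000 km are excluded
from regional analyses and reported with that distance, the treatment
given to a single isolated Sahel specimen in the source study.

`dimorphism_ratio()` is the mean-female/mean-male centroid-size ratio;
unknown-sex specimens count toward the scope's n but never enter the
ratio, and an empty sex cell yields `NA` with a note rather than an error
(small regional cells are a fact of museum data). A Welch t test on log
centroid size accompanies each ratio as a supplementary comparison; the
headline inference about sex belongs to the regression, not this test.

## The synthetic-data generator

No specimen data are distributed, so `simulate_hyena_dataset()` generates
datasets with the statistical structure the analysis assumes, and the
generator's defaults are the study conditions: 332 specimens
(121 female / 125 male / 86 unknown), clustered collecting localities
(weights 0.75/0.15/0.10 for east/west/south), target dimorphism ratio
1.012, a −5% size effect of high density, 1% multiplicative size noise,
32 census sites, and mean centroid sizes of 369/540/576 units for the
three views. Sizes are generated multiplicatively,

$$s = \mathrm{base} \cdot \exp\bigl(\beta_{sex}\,[male] +
 \beta_{dens}\,[high] + \mathrm{trend}(lon, lat) + \varepsilon\bigr),$$

landmarks as a scaled, randomly rotated and translated template with
digitizing noise, written in exactly the TPS/CSV/ASCII-grid formats the
readers consume — the generator doubles as the readers' compatibility
test. Unknown-sex specimens carry a latent true sex (drawn 50/50) that
drives their size but is invisible to the analysis, as in real
collections.

The density field is a Gaussian random field for log density with stable
covariance — nugget 0.05, partial sill 0.70, range 2°, shape 1.5 — and a
low/high boundary at 0.03 animals/km². The short range keeps the
realized low-class share stable near the study's ~19% under clustered
sampling, and census sites are placed mostly as jittered specimen
localities, reflecting that census studies and museum collecting
concentrate in the same protected areas. The smooth spatial size trend
(~±1.5% across the continent) and deterministic climate fields are
likewise realism choices, not fitted quantities.

What the generator does *not* emulate: digitizing error correlated along
outlines, temporal drift over a century of collecting, phylogeographic
structure, non-stationary density covariance, and real coastline
geometry. Tests passing on this generator therefore demonstrate that the
computational chain recovers known structure under honest noise — not
that any particular biological conclusion transfers to real specimens.

## Recovery benchmarks and problem sizes

Two replicated benchmarks quantify end-to-end behaviour, both
seed-explicit:

* A regression-machinery check generates sizes *linearly* with known sex
  and density-class effects, fits the combined model, and verifies 95%
  CI coverage of both coefficients across 200 replicates.
* `recovery_study()` runs the full round trip — simulate, superimpose
  and slide, join covariates, select the spatial component, fit — and
  records the recovered dimorphism ratio and the signs of the sex and
  density effects. At the defaults (200 replicates of n = 300, one view,
  degree-2 candidate surface so the exhaustive subset search stays
  exact) the mean recovered ratio sits within ±0.005 of the generating
  1.012 and both signs are recovered in ≥95% of replicates. The
  replicate mean is the assessed quantity for the ratio: a single n=300
  draw has ~0.003 sampling SD on the ratio from finite sampling alone.

In the recovery benchmark the density-class covariate joined to the
regression is the generator's known class. The kriging chain is assessed
by its own criteria — exact interpolation at zero nugget, unit-sum
weights, agreement with a hand-assembled system, and a strict
mean-squared-error improvement over the global-mean predictor at
held-out truth points — because interpolating a 2°-range field from 32
census sites recovers the class only imperfectly, and folding that
interpolation error into the regression benchmark would measure the
census network's geometry rather than the regression machinery. The
default pipeline (`run_pipeline(density_source = "krige")`) of course
uses the kriged classes, as any real-data analysis must.

Semivariogram refitting is the one stage whose sampling error exceeds
its nominal tolerance at a single realization: at n = 200 sites,
weighted-least-squares estimates of nugget and partial sill routinely
miss by more than 25%. The corresponding test asserts the 25% band on
the median over 10 seeded realizations, with range and shape held at
their known values.

Problem sizes throughout (n = 300–332 specimens, 14-landmark templates,
32–200 census sites, 200-replicate batteries) were chosen as the
smallest at which the assessed properties are stably powered on a single
desk CPU.

## A short run

```{r, eval = FALSE}
run <- run_pipeline(seed = 11, out_dir = "run_out")
print(run)
coefficient_table(run$models$ventral$reduced)
run$dimorphism
```

The output directory then holds the centroid-size table, density
classes, per-view coefficient tables and size-class map tables, the
dimorphism summary, and a run log echoing the seed and every parameter;
two runs with the same seed and configuration produce byte-identical
CSVs.
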