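# hyenamorph

Geographic variation in skull size, end to end: from 2D landmark files to
spatial regression tables. `hyenamorph` is an R package for
macroecological analyses of museum skull collections in which the size
variable is landmark-based **centroid size** and the explanatory
structure is geography, climate, habitat, population density and sex.

It was built around the analysis design of a continental study of
spotted-hyena (*Crocuta crocuta*) skulls, and implements every
computational stage of that design as reusable, tested functions:

* **Morphometrics** — TPS (tpsDig dialect) reading/writing, generalized
  least-squares Procrustes superimposition (proper rotations only),
  thin-plate-spline bending energy, sliding semilandmarks along
  chord tangents to minimize bending energy, centroid size
  `CS = scale * sqrt(sum_i ||p_i - mean(p)||^2)`.
* **Density surface** — empirical semivariograms, the stable model
  `gamma(h) = nugget + psill * (1 - exp(-(h/range)^s))`, universal
  kriging with polynomial drift, Fisher–Jenks optimal classification,
  and the 4-class-to-low/high density reduction.
* **Size models** — trend-surface candidates `X^i Y^j` (per-coordinate
  degree ≤ 4, 24 terms), exhaustive/stepwise AIC subset selection,
  combined covariate models (sex, temperature, precipitation, density
  class, land cover), VIF, backward stepwise AIC reduction of spatial
  terms, Shapiro–Wilk / Durbin–Watson / Cook's distance / ACF
  diagnostics.
* **Dimorphism** — mean-female/mean-male centroid-size ratios, total and
  by deterministic geographic regions, with isolated-specimen exclusion.
* **Synthetic data** — a seed-explicit generator reproducing the study
  conditions (332 specimens, 121/125/86 sex counts, clustered sampling,
  dimorphism 1.012, −5% high-density size effect), which writes the
  exact file formats the readers consume.

A transcription of the published 32-study density compilation ships in
`inst/extdata/density_studies.tsv` (densities 0.005–1.65 hyenas/km²; the
coordinates in that file are approximate gazetteer positions added here
and labelled synthetic).

## Worked example

```r
library(hyenamorph)
run <- run_pipeline(seed = 11, out_dir = "run_out")
print(run)
```

```
Skull-size pipeline run (seed 11): 332 specimens, views: ventral, lateral_cranium, lateral_mandible
Density classes (Jenks k = 4 reduced to 2):
  low : 0.01588 to 0.08315 (n = 140)
  high: 0.08376 to 0.4326 (n = 192)
Dimorphism ratios (total):
  ventral           1.0116 (F 121; M 125)
  lateral_cranium   1.0108 (F 121; M 125)
  lateral_mandible  1.0118 (F 121; M 125)
```

The dimorphism ratios are mean-female/mean-male centroid size: the
generator plants a 1.2% female size advantage (ratio 1.012), and this
run recovers 1.0108–1.0118 across the three views. The density classes
are the Jenks low/high split of the kriged density surface at the
specimen localities.

```r
co <- coefficient_table(run$models$ventral$reduced)
co[co$variable %in% c("sexmale", "density_classhigh"), ]
```

```
            variable  estimate        se         t            p
12           sexmale -4.960688 0.8753135 -5.667329 3.294120e-08
16 density_classhigh -6.723457 0.9836148 -6.835458 4.300892e-11
```

Both planted effects come back negative and significant: males smaller
than females (generating value ≈ −4.4 size units at a mean size of 369)
and high-density specimens smaller than low-density ones (attenuated
from the generating −18.4 because the density class here is itself
estimated by kriging + Jenks, not known). `run_out/` holds the
centroid-size table, density classes, per-view coefficient and
size-class map tables, the dimorphism summary and a run log; re-running
with the same seed reproduces the CSVs byte for byte.

A thin CLI wraps the same functions:

```sh
Rscript scripts/hyenamorph-pipeline.R all --seed 11 --out run_out
```

## Package layout

| Area | Key functions |
|---|---|
| IO | `read_tps`, `write_tps`, `read_density_table`, `read_specimen_table`, `read_slider_table`, `read_ascii_grid`, `extract_covariates` |
| Morphometrics | `centroid_size`, `gpa_align`, `bending_energy_matrix`, `slide_semilandmarks` |
| Spatial | `great_circle_km`, `empirical_semivariogram`, `variogram_model`, `stable_semivariance`, `fit_variogram`, `universal_krige`, `jenks_breaks`, `categorize_density`, `collapse_landcover` |
| Models | `build_trend_terms`, `trend_design`, `fit_ols`, `select_spatial_model`, `vif`, `backward_stepwise_aic`, `diagnostics` |
| Dimorphism | `region_scheme`, `assign_region`, `dimorphism_ratio`, `dimorphism_table` |
| Synthesis & pipeline | `sim_config`, `simulate_hyena_dataset`, `write_sim_dataset`, `run_pipeline`, `recovery_study`, `size_classes` |

The methods vignette (`vignettes/skull-size-macroecology.Rmd`) documents
the models, parameter defaults, numerical conventions and known
limitations in detail.
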