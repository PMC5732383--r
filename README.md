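# hzclines

Tools for quantifying the position, width and temporal movement of hybrid-zone
clines from unevenly sampled museum specimens — the situation where a century
of opportunistic collecting holds the history of a contact zone, but no one
ever sampled fixed sites repeatedly, so site-based cline-fitting software
(HZAR, Analyse, ClineFit) cannot be used.

The package was built around an Andean tanager hybrid zone in which a larger
black-and-scarlet highland form meets a smaller yellow-rumped lowland form
along a ~135 km transect, but every component is generic:

- **Transect projection** — fit a transect line to specimen localities by
  regression of latitude on longitude, project each specimen to a distance
  (km) from the coastal origin, assign sectors, localities (1-km
  single-linkage clusters) and collection periods.
- **Phenotypes** — body-size scores via correlation-matrix PCA of six
  morphometric characters; brightness, chroma and hue from 400–700 nm
  reflectance spectra by segment classification.
- **Cline fitting** — the four-parameter log-logistic (Hill) curve

  `Y = C + (D − C) / (1 + exp(B (log X − log E)))`

  fit by profiled multi-start least squares. Center = ED50 = `E`; width =
  `ED90 − ED10 = E (9^(1/|B|) − 9^(−1/|B|))`, the stretch of transect outside
  which essentially only parental phenotypes occur.
- **Uncertainty and movement** — bootstrap over specimens with the
  center-retention rule (replicates kept only when the refit center lies in
  0–140 km), percentile CIs, and cross-period ANOVA + Tukey comparisons of
  bootstrap distributions.
- **Population genetics** — haplotype summaries, pairwise-difference
  matrices, and three-level AMOVA (sectors / localities / individuals) with
  F_CT, F_SC, F_ST and the standard permutation tests.
- **Neutral diffusion** — expected cline width `σ√(2πT)` after `T`
  generations, with scenario envelopes to ask whether observed widths are
  narrower than neutrality allows (the tension-zone diagnostic).
- **Synthetic data** — a generator with known ground truth emulating the
  study's sampling structure, so the entire pipeline is testable end to end.

## Worked example

Simulate a modern collection series, fit the body-size cline, and bootstrap
its parameters:

```r
library(hzclines)

sim <- simulate_specimens(sim_config(), seed = 42)
dat <- subset(sim$latent, period == "P2010")

fit <- fit_hill(dplyr::rename(dat, value = pc1_trait), value,
                trait = "PC1", period = "P2010")
fit
#> Hill-function cline fit [PC1, P2010]
#>   C = -1.488  D = 1.56  B = -11.64  E = 77.88 km
#>   center = 77.78 km, width = 29.57 km, SSE = 4.402, n = 45, converged: TRUE

bt <- bootstrap_cline(dplyr::rename(dat, value = pc1_trait), value,
                      reps = 300, seed = 7, trait = "PC1", period = "P2010",
                      point_fit = fit)
bt
#> Bootstrap cline distribution [PC1, P2010]
#>   retained 300 / 300 replicates (centers filtered to [0, 140] km)
#>   center: 77.88 km (95% CI 74.91-80.59)
#>   width: 28.97 km (95% CI 21.91-36.19)
```

The fitted plateaus (`C`, `D`) are the parental trait values at the two ends
of the transect, the center (77.8 km) is where the transition is steepest,
and the width (≈ 30 km) is the stretch over which intermediate phenotypes
occur — here recovering the generator's configured truth (center 76.7 km,
width 33.1 km) within bootstrap uncertainty. Compare that width with the
neutral-diffusion envelope for a 6000-year-old zone with dispersal 1–20
km/generation and generation time 1–2 years:

```r
width_envelope(c(1, 20), c(1, 2), age_yr = 6000)[, c("min_km", "max_km")]
#>   min_km max_km
#>     137.  3883.
```

A fitted width of ~30 km sits far below the smallest neutral expectation —
the signature of a tension zone maintained by selection.

`run_pipeline(run_config(), out_dir, seed)` runs everything (simulation or
real input files → transect → phenotypes → clines → bootstrap → comparisons →
AMOVA → diffusion report) and writes a plain-text result bundle with a
hash/seed manifest; reruns with the same seed are byte-identical. Fitted
objects have `tidy()`, `glance()` and `autoplot()` methods. A thin CLI
wrapper lives in `inst/scripts/run-pipeline.R`.

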