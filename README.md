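# retscat

Correlation and layer analysis for co-registered retinal a/LCI + OCT.

Angle-resolved low-coherence interferometry (a/LCI) measures depth-resolved
angular distributions of light scattered by tissue. In the retina, with an
OCT B-scan co-registered to the same location, each anatomical layer — nerve
fiber layer (NFL), outer plexiform layer (OPL), retinal pigmented epithelium
(RPE) — can be isolated in depth and its 2D angular scattering distribution
analyzed for structural signatures of disease. `retscat` implements that
analysis chain for researchers studying tissue-scale biomarkers (e.g. of
neurodegeneration) in rodent retina, together with a fully parameterized
synthetic-data generator with ground truth, so every stage is testable end
to end.

The core quantities:

* **Two-point spatial correlation.** The Fourier transform of the angular
  scattering distribution yields the two-point spatial correlation of the
  optical field. Azimuthal integration gives radial correlation energy
  C(r); over a length-scale window (2–10 µm short-range by default) it
  follows a power law C(r) ∝ r^(−α), and the fitted log–log slope α gives
  the tissue fractal dimension **FD = 3 − α**. A faster loss of spatial
  correlation (higher α, lower FD) indicates reduced structural
  self-similarity.
* **Intensity statistics.** Masked histogram moments (mean, population
  variance, skewness, excess kurtosis) of the per-layer angular intensity.
* **Layer morphology.** Automated NFL/OPL/RPE boundary segmentation of
  B-scans, layer thicknesses, and registration of OCT boundaries into
  a/LCI depth pixels via the pixel-to-depth conversion factor.
* **Group inference.** Mixed repeated-measures ANOVA comparing two cohorts
  (WT vs AD) of eyes × 8 retinal locations, exact under compound symmetry
  in the balanced case, with the within-eye correlation ρ estimated from
  variance components, Shapiro–Wilk and Brown–Forsythe assumption checks,
  and quadrant-stratified (superior/inferior/nasal/temporal) analyses.

## Worked example

```r
library(retscat)

cfg <- optical_config()          # lambda = 0.830 um, 64x64 angles, 1 um lag pixel
spec <- medium_spec(alpha_true = 1.0, seed = 7)
plane <- make_angular_plane(spec, cfg)

corr  <- angular_to_correlation(plane, cfg)
curve <- azimuthal_integrate(corr)
fit_slope(curve, window = c(2, 10))
#> Power-law fit [2, 10] um: alpha = 1.000 (FD = 2.000), R2 = 1.000, n = 8
```

The synthesized plane's correlation-energy curve follows r^(−1) over the
2–10 µm window, and the fit recovers α = 1.000 with FD = 3 − α = 2.000 —
the generator and analyzer share one coordinate convention, so closed-loop
recovery is essentially exact.

A full study-scale run (10 WT vs 13 AD eyes × 8 locations, disease
direction configured as thinner AD NFL, higher AD α in all layers, AD NFL
intensity elevation confined to the superior quadrant):

```r
run <- run_pipeline(run_config(spec = cohort_spec(seed = 20260927)))
print(run)
#> Pipeline run (seed 20260927): 184 generated, 184 analyzed, 0 dropped
#> Significant group effects (unstratified):
#>   alpha / NFL: AD>WT, p = 2.205e-26
#>   alpha / OPL: AD>WT, p = 2.72e-27
#>   alpha / RPE: AD>WT, p = 4.504e-18
#>   thickness_um / NFL: AD<WT, p = 1.706e-12
#>   intensity_mean / NFL: AD>WT, p = 2.484e-26
#>   ...
```

Each line is one metric × layer group comparison: the AD cohort shows a
significantly higher correlation slope in all three layers (faster loss of
spatial correlation, lower fractal dimension), a thinner NFL, and elevated
NFL scattering intensity; quadrant rows in `run$stats` localize the
intensity effect to the superior locations. Metrics with no configured
effect can still cross α = 0.05 occasionally — the tests are unadjusted,
so such rows are expected type-I events.

The numbered scripts under `analysis/` walk the same ground as separate
narrative steps (simulate → spectral round trip → pipeline → group
statistics → operating characteristics), writing their tables under
`results/`.

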