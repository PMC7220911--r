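---
title: "Methods: correlation and layer analysis for retinal a/LCI + OCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlation and layer analysis for retinal a/LCI + OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retscat)
```

## The measurement model

Angle-resolved low-coherence interferometry (a/LCI) records scattered
intensity as a function of wavenumber and scattering angle. A Fourier
transform along the spectral dimension converts interferometric fringes
into depth, so each acquisition yields a depth-resolved angular scattering
distribution; scanning the second angle with a galvanometer builds a
depth-resolved stack of 2D angular planes. Co-registered OCT B-scans
provide the anatomy: the nerve fiber layer (NFL), outer plexiform layer
(OPL) and retinal pigmented epithelium (RPE) are segmented in the B-scan
and their boundaries rescaled into a/LCI depth pixels, isolating one 2D
angular scattering plane per retinal layer.

Two parallel analyses are applied to each layer's plane:

* **Spatial correlation.** The Fourier transform of the angular scattering
  distribution yields the two-point spatial correlation of the optical
  field. The magnitude of the centered 2D DFT is azimuthally integrated
  (summed over annuli of radial lag) into a correlation-energy curve
  $C(r)$; over a window of length scales the curve follows a power law
  $C(r) \propto r^{-\alpha}$ and the fitted log–log slope $\alpha$ is
  related to the tissue fractal dimension by $\mathrm{FD} = 3 - \alpha$.
  The short-range window (2–10 µm by default) targets cellular and
  sub-cellular structure; a long-range window (20–100 µm) is available
  when the lag axis supports it.
* **Intensity histogram.** The masked pixel intensities of the plane give
  mean, population variance (divisor $N$), skewness and excess kurtosis.
  Moments are computed from the raw retained pixels — exactly the
  singleton-bin limit of count-weighted ($k/N$) histogram formulas — so
  binning introduces no bias; the histogram itself is a reporting
  artifact.

Group inference compares a wild-type (WT) and a disease-model (AD) cohort
of eyes, each sampled at 8 retinal locations, with a mixed
repeated-measures ANOVA under compound symmetry (below).

## Coordinate convention

One small-angle convention is used by the generator and the analyzer: an
angle $\theta$ maps to spatial frequency $q = \theta/\lambda$ (cycles per
micron). A plane sampled over a total span $\Theta$ per axis therefore has
spatial-lag spacing $\delta r = \lambda/\Theta$ and inscribed-circle
maximum lag $r_\max = (n/2)\,\delta r$ for $n$ angular samples. The
default configuration (`optical_config()`) uses $\lambda = 0.830$ µm and
chooses $\Theta = \lambda$ (radians) so that $\delta r$ is exactly 1 µm,
placing 8 lag samples in the default 2–10 µm fit window; testability of
the inverse problem takes precedence over replicating any particular
instrument geometry.

## What the synthetic generator emulates

No measured retinal data ship with the package; every input is synthetic
with recorded ground truth.

**Angular planes with prescribed correlation.** Planes are synthesized in
the correlation domain. The radial lag grid is partitioned into annuli of
width $\delta r$; target annulus energies $E_b \propto r_b^{-\alpha}$ are
split evenly over each annulus's pixels (so the azimuthally *summed*
curve follows the law by construction, which a smooth per-pixel
$r^{-(\alpha+1)}$ profile does not achieve on a discrete grid — its
binning bias exceeds 10%). Below `inner_scale` the profile plateaus; the
law is guaranteed on `[inner_scale, outer_scale]`. The target magnitude
receives Hermitian-symmetric random phases (unit-modulus factors from the
FFT of white noise), is inverse-transformed to a real field $z$,
standardized, and mapped to intensities
$\mathrm{amplitude} \cdot \max(1 + \tau z,\ 0)$ with texture contrast
$\tau = 0.3$. Two consequences matter:

* the clip at zero touches only the far Gaussian tail
  ($P(z < -1/\tau) \approx 4\times10^{-4}$), so the recovered correlation
  equals the target almost exactly, and — because the marginal
  distribution of $z$ is Gaussian regardless of $\alpha$ — the pixel
  intensity moments are statistically independent of the correlation
  slope, preventing crosstalk between the correlation and intensity
  analyses of a cohort;
* the mean offset contributes only to the zero-lag bin, which is excluded
  from every fit.

**Raw scans.** A reflector at depth pixel $m$ is encoded as $m$ cosine
cycles across the sampled wavenumber band (reflectivity may carry angular
structure), plus optional additive Gaussian read noise — the standard
detector-noise model for spectral-domain interferometry. Depths at or
beyond the Nyquist pixel $n_k/2$ are rejected.

**B-scans.** A piecewise-constant axial template with three bright bands
(NFL, OPL, RPE) over dimmer gaps, multiplied by
$1 + s\,(E - 1)$ with $E \sim \mathrm{Exp}(1)$ — fully developed
multiplicative speckle at $s = 1$, attenuated speckle below. Ground-truth
boundaries are the exact template rows, 0-based and half-open.

**Cohorts.** Per eye and layer, ground-truth slope, thickness and
intensity are drawn as group mean plus location-level deviations with an
exchangeable (compound-symmetric) correlation $\rho$ across the 8
locations, sampled exactly via the two eigenspaces of the CS matrix. The
default $\rho = -0.14$ reflects a small negative within-eye dependence;
note that for $k = 8$ the admissible CS range is
$(-1/7, 1) \approx (-0.1429, 1)$, so the default sits just inside the
boundary (a boundary-rounded estimate such as $-0.1429$ would make the
covariance non-positive-definite and cannot be simulated). Intensity
variation is dominated by a common-mode per-(eye, location) factor shared
by the three layers (sd 0.10) — physically, coupling and illumination
efficiency vary per location and multiply all layers alike — on top of
small layer-specific fluctuations (sd 0.03). The default disease
configuration encodes: AD NFL thinner (16 vs 18 µm), AD slope higher by
0.25 in all three layers, and an AD intensity elevation of 0.5 confined
to the superior locations of the NFL (which also elevates the whole-eye
NFL mean and, through the multiplicative texture, the NFL pixel
variance). The 8 locations are the ±500 and ±1000 µm offsets along the
two axes, with +Y superior, −Y inferior, +X nasal, −X temporal.

**What it does not emulate.** No 3D wave propagation (first-Born or
otherwise), no eye-optics aberrations or dispersion, no depth-dependent
signal decay, no spectrometer nonlinearity, and the angular-plane texture
is a phase-randomized Gaussian surrogate rather than physical speckle.
Passing tests therefore demonstrate that the *analysis chain inverts the
stated forward model* and that the statistics have their nominal
operating characteristics — not that the pipeline is robust to every
systematic present in measured retinas.

## Numerical choices

* **Rounding and indexing.** Pixels are 0-based; intervals half-open
  `[top, bottom)`. The OCT-to-a/LCI mapping rounds half away from zero and
  widens zero-height mapped intervals to one depth pixel; intervals past
  the volume depth are clamped with a warning.
* **Depth transform.** Hann apodization by default (`"none"` for
  oracle-exact tests). DC suppression subtracts each column's spectral
  mean, emptying the depth-0 bin without touching finite-depth fringes.
  Magnitudes are scaled by $2/(n_k \cdot \overline{w})$ so a
  unit-amplitude fringe gives a unit peak (depth-0 not doubled); magnitude
  (not squared magnitude) is carried forward into all intensity
  statistics, as a documented convention.
* **Within-layer depth aggregation** is the mean (thin and thick layers
  stay comparable); `agg = "sum"` integrates instead.
* **Correlation curves** exclude the zero-lag pixel and report only
  complete annuli (bins extending past the inscribed circle of the lag
  grid would be corner-truncated and biased low). "Correlation energy" is
  the annulus-summed magnitude of the complex correlation.
* **Masking.** Specular artifacts are thresholded at median + 6 MAD
  (robust under heavy-tailed speckle), connected, and dilated by 2 px;
  explicit user masks override. Masked pixels are filled with the
  retained-pixel median before the transform (zero-fill available); with a
  common mask the exclusion is exact (metrics of an artifact-injected and
  a clean plane agree to machine precision), while comparison against the
  unmasked clean plane retains a patch-removal sampling bias at the
  percent level because the texture is long-range correlated.
* **Slope fits** use ordinary least squares of $\log_{10}$ energy on
  $\log_{10}$ lag, need at least 4 usable bins, and report
  $\mathrm{FD} = 3 - \alpha$ identically. Fits are per scan; statistics
  are then taken over scans (fitting a per-layer average curve first is
  the alternative reading; per-scan fitting preserves record-level
  variability for the repeated-measures model).
* **Seeds.** One master seed derives per-stage, per-record child seeds by
  a documented counter scheme (`derive_seed()`), so cohorts, planes and
  noise realizations reproduce bit for bit and partial reruns are stable.

## The group test

For a balanced design (every eye measured at the same $k$ locations) the
between-group test is computed from sums of squares:
$F = \mathrm{MS}_\mathrm{group} / \mathrm{MS}_\mathrm{eye(group)}$ with
$(1,\ n_\mathrm{eyes} - 2)$ degrees of freedom, which is exact under
Gaussian compound symmetry (eye means are then iid within group), and

$$\hat\rho = \frac{\mathrm{MS}_\mathrm{eye} - \mathrm{MS}_\mathrm{within}}
{\mathrm{MS}_\mathrm{eye} + (k-1)\,\mathrm{MS}_\mathrm{within}},$$

reported as-is when negative. Unbalanced tables (e.g. after record drops)
fall back to a Welch two-sample test on eye-level means, flagged
`balanced = FALSE` — an approximation of a full mixed-model fit that
keeps the eye as the independent unit. Assumption checks follow the
analysis plan of the study design: Shapiro–Wilk on group-mean-centered
residuals at a Bonferroni-corrected $\alpha = 0.003$ (centering by group
means rather than eye means preserves the shape of the error
distribution that the check is meant to probe), and Brown–Forsythe
Levene on eye-level means at $\alpha = 0.05$. Primary effects are
reported unadjusted at $\alpha = 0.05$; the Bonferroni correction is
applied to the normality family only. Quadrant-stratified analyses rerun
the same test on location subsets; a single-location subset collapses to
a comparison of eye values with $\hat\rho$ undefined.

## Validation problem sizes

The test suite and the acceptance script validate, at sizes chosen to
exercise each property well inside a desktop budget: the FFT correlation
against a brute-force DFT double sum on 32×32 planes; closed-loop slope
recovery for $\alpha \in \{0.4, 0.8, 1.2, 2.0\}$ over 20 seeds each;
moment formulas against direct sums on 100 random planes; the group
test's type-I error over 2000 null cohorts at the 10-vs-13 × 8 design;
$\hat\rho$ recovery over 200 replicates at
$\rho \in \{-0.14, 0, 0.3\}$; the full disease-direction pattern over 50
cohort replicates; and segmentation exactness (noiseless) plus mean
absolute boundary error under speckle 0.3 over 100 seeds. The
direction-suite success probability is structurally bounded near 0.90:
each replicate requires, besides the true effects, that four null
intensity tests (OPL/RPE mean and variance) all stay non-significant at
$\alpha = 0.05$; the common-mode intensity factor makes the four tests
strongly dependent (roughly two effective nulls, $0.95^2 \approx 0.90$),
which is what makes the criterion attainable at all.

## Known limitations

* The balanced-path F test is exact only under compound symmetry; other
  within-eye covariance structures are out of scope.
* The automated segmenter assumes three resolvable bands; complex retinal
  pathology (e.g. folds) is outside its design envelope and surfaces as
  record drops.
* Angular planes are treated as anisotropy-free (azimuthal integration);
  directional correlation analysis is a non-goal.
* Data interchange is CSV/YAML plus in-memory structured objects; the
  package does not define an on-disk array container.
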