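---
title: "Correlative mineral-density and elemental-ratio mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlative mineral-density and elemental-ratio mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdxrf)
```

## The problem

Clinical and benchtop computed tomography commonly reports a single mineral
density for a calcified tissue, yet diseased dental tissues — carious dentin,
periodontitis-affected cementum, dental calculus — are mixtures of hypo- and
hypermineralized volumes. `mdxrf` implements a two-instrument analysis that
(i) calibrates micro-CT attenuation to hydroxyapatite-equivalent mineral
density (MD, mg/cc) with density phantoms, (ii) discretizes tomograms into
statistically distinct mineral zones with a locus-seeded watershed, (iii)
quantifies X-ray fluorescence (XRF) maps of Ca, P and Zn into volume
concentrations, and (iv) correlates segmented MD with per-pixel Ca/P and
Ca/Zn molar ratios. Because specimen-level instrument data are not
redistributable, a synthetic generator with complete ground truth stands in
for both instruments; every stage is tested as a recovery problem against
that truth.

## Calibration model

Raw reconstructed intensities are first rescaled to Hounsfield units under
the convention used throughout the package: **air at 0 HU, water at
1000 HU** (the standard HU scale shifted by +1000),

$$\mathrm{HU} = 1000\,\frac{I - I_{\mathrm{air}}}{I_{\mathrm{water}} - I_{\mathrm{air}}},$$

with linear extrapolation outside the anchors, so mineralized tissue sits
well above 1000 HU. Sidecar metadata records the convention so standard-HU
data can be imported with a constant offset.

Phantoms of known density (defaults 0, 250, 500, 747, 750, 1136 and
3080 mg/cc) are measured with `phantom_roi_stats()` and fitted by ordinary
least squares of MD on mean HU (`fit_calibration()`), the direction in which
the curve is later applied. The fit is unweighted by default — the phantom
ROIs are large and homogeneous, so the HU means have comparable precision —
with an inverse-variance option (`weighted = TRUE`). The generator's default
truth is

$$\mathrm{MD}\,(\mathrm{mg/cc}) = 0.11\,\mathrm{HU} - 48.6,$$

and the companion gravimetric (ash) reference line has the same slope with
intercept −17.3, so the CT-vs-ash residual is a constant −31.3 mg/cc and the
two lines' predictions correlate perfectly. `compare_with_gravimetric()`
reports both the residual curve over the phantom HU range and the Pearson
correlation of predictions; because "correlation between two lines" is not
operationally unique, the point-pair correlation is co-reported.

Negative MD (possible below ~442 HU) is preserved and flagged, never
clamped: clamping would bias segment means near soft-tissue boundaries.

## Segmentation

The segmentation view is the joint histogram of voxel intensity and gradient
magnitude (`histogram2d()`). Homogeneous material phases form high-count
columns at low gradient; interfaces form arches connecting columns at
elevated gradient. Seed *loci* are rectangles in this plane: all voxels whose
(intensity, gradient) pair falls inside a locus become the markers of one
region. `select_seed_loci()` validates manual boxes or finds them
automatically: the low-gradient band (below the `gradient_quantile` of the
gradient marginal, default 0.5) is collapsed to an intensity histogram,
lightly smoothed, and local maxima separated by at least
`min_separation_bins` (default 8 of 128 bins) and at least `peak_frac`
(default 5%) of the tallest peak become loci.

`watershed_segment()` floods the gradient-magnitude landscape from the
markers (Meyer's priority flood, 6-connectivity, implemented in C++).
Determinism matters for reproducibility, so ties are broken explicitly: the
queue is ordered by (gradient value, linear voxel index) and a voxel keeps
the label it is first reached with. A pure-R brute-force flood with the same
semantics serves as the oracle in the test suite; the two agree exactly on
hundreds of randomized small volumes, including heavily tied landscapes and
masked volumes.

Numerical choices:

* **Gradient operator** — central differences (exact on linear ramps, which
  makes analytic tests possible), with edge replication at faces. A Sobel
  operator adds smoothing but no accuracy on the piecewise-smooth volumes
  targeted here.
* **Iterative locus refinement** — the loop "edit loci, re-segment, check
  that segment means are statistically distinct" is left to the user (or a
  script): all the pieces (`segment_stats()`, `t_test()`) are exposed.

Per-segment statistics convert HU to MD through the affine calibration:
means map exactly, standard deviations scale by |slope|, ranges map the HU
extremes. Whether one averages HU then converts, or converts per voxel then
averages, is immaterial for an affine map — this is why segment means are
computed in HU first.

Dentin segments are additionally classified by mean HU into hypomineralized
(3545–13475 HU), near-normal (13755–14740 HU) and hypermineralized
(>15000 HU, strictly above the open-ended threshold) zones; values in the
gaps are flagged unclassified rather than force-assigned.

## XRF quantification

Raw counts divide by the thin-film-standard gain to give area concentration
(mmol/cm²), then by the **self-absorption effective thickness** to give
volume concentration (mmol/cm³). The single-layer uniform-matrix
Beer–Lambert model is used:

$$t_{\mathrm{eff}} = \frac{1 - e^{-\mu_{\mathrm{tot}} t}}{\mu_{\mathrm{tot}}},
\qquad
\mu_{\mathrm{tot}} = \frac{1/L_{\mathrm{in}}}{\sin\theta_{\mathrm{in}}}
                   + \frac{1/L_{f}}{\sin\theta_{\mathrm{out}}},$$

where $t$ is the specimen thickness, $L_{\mathrm{in}}$ the absorption length
at the incident energy (default 10 keV), $L_f$ the absorption length at the
element's fluorescence line, and the angles default to the common 45°/45°
microprobe geometry. $t_{\mathrm{eff}} \le t$ always, converging to $t$ in
the thin-sample limit (within 1% when $\mu_{\mathrm{tot}} t < 0.02$) and
saturating at $1/\mu_{\mathrm{tot}}$ for thick specimens. Absorption lengths
are **inputs** (a config table per element), not computed from matrix
stoichiometry; the defaults shipped for Ca/P/Zn in an apatite-like matrix
are synthetic placeholders of plausible magnitude, and quantitative work
must supply measured values. The generator's forward model applies exactly
this factor, so `calibrate_counts()` + `thickness_correct()` is its true
inverse — noiseless round trips agree to numerical precision.

Units are tracked on every map (`counts`, `mmol_cm2`, `mmol_cm3`) and
arithmetic between maps of different units is rejected outright.

## Ratio maps and masked statistics

`map_math()` performs pixelwise arithmetic; division returns a ratio map
whose validity mask excludes pixels with the denominator at or below a
detection floor (motivated by the weak P fluorescence signal at these
energies). `masked_stats()` reports the **mean of per-pixel ratios** by
default — the reading of "map math then averaging" — and the
ratio-of-means convention is always available and recorded, because the two
differ under noise (ratio-of-means is biased low by roughly the squared
coefficient of variation of the composition noise). For constant-ratio
fields the two agree exactly, which is tested.

`density_plot()` builds the joint two-element histogram within a mask and
detects concentration clusters: local maxima at least 3 bins apart each
holding at least 5% of the masked counts. Two or more peaks flag "localized,
distinct zones" (as in hypomineralized lesion zones); a single peak flags a
spread population. `bicolor_overlay()` and `line_profile()` are pure views —
percentile-normalized composites and bilinear profile sampling — that never
alter stored data. `md_vs_ratio_correlation()` fits the per-tissue mean
ratio on mean MD (OLS, Pearson r, residuals), the cross-modality summary
plot of the analysis.

## Statistics

Between-group comparisons use two-sided t tests (`t_test()`): Welch by
default for unpaired data (pooled-variance optional), paired where
measurements are linked (e.g. CT vs ash on the same phantoms). Bonferroni
correction takes an **explicit family size** `m >= number of tests`
(`bonferroni()`), because the dentin analyses adjust over the full set of
pairwise zone comparisons even when only a subset is reported. The
"median-based ANOVA" across ROIs is implemented as Mood's median test —
counts above/below the grand median, chi-squared without continuity
correction — with a Fisher-exact option for small tables and Kruskal–Wallis
as a configurable alternative reading. `build_report()` merges segment and
ratio statistics per tissue and flags statistically indistinguishable pairs.

## The synthetic generator

The generator emulates, with full ground truth:

* **Phantom volumes** — cylindrical inserts of the seven default densities
  on an air background, mapped MD → HU → raw through the true line and the
  acquisition anchors (arbitrary detector units; air 100, water 612 by
  default — only their difference matters).
* **Tissue volumes** — axis-aligned regions with voxel MD drawn
  Normal(mean, sd), optional linear mean ramps, sharp steps as adjacent
  regions. Defaults transcribe the hard-tissue table shipped in
  `tissue_md_defaults()`: enamel 2957.5, dentin 1535, cementum 1290 ± 15,
  bone 1115 ± 30, diseased cementum 1150 ± 50, hypomineralized dentin
  915 ± 20, hypermineralized dentin 2255 ± 50, calculus 1525 ± 40 mg/cc.
  Where a published mean ± sd existed it is used as the voxel-level scatter;
  where only a range existed the mean is the midpoint and the scatter a
  quarter of the range. Using a between-specimen sd as within-volume scatter
  is a modeling choice: it keeps each fixture's voxel distribution centered
  on the tissue's reported mean with realistic spread.
* **Acquisition** — Gaussian blur (separable, truncated at 3σ, edge
  renormalized) **then** additive Gaussian HU noise: the point-spread
  function acts on the signal, counting noise on the detected values. The
  published description does not constrain the noise character; Gaussian HU
  noise with sd 50 is the recorded assumption. Voxel size defaults to
  3.84 µm.
* **XRF maps** — per-region base Ca concentration (scaled from MD by the Ca
  content of stoichiometric hydroxyapatite, ≈31.5 mmol/cm³ at 3160 mg/cc)
  times a shared mean-one Gaussian amplitude factor; P and Zn derived as Ca
  divided by the regional ratio times an independent mean-one composition
  factor. Parameterizing composition noise **on the ratio field** makes the
  per-pixel ratio mean equal the configured ratio by construction, so
  masked-mean recovery is unbiased; putting independent noise on each
  element instead would inflate the mean of per-pixel ratios by about the
  squared noise cv, which is a property of that noise model, not of the
  tissue. Band layouts (alternating acellular/cellular cementum) and lesion
  layouts (severe zone, transition zone, normal base) are provided; the
  forward model includes the same self-absorption factor the quantification
  inverts, a Poisson counting-noise option and a thin-limit flag.

Every stochastic generator call takes an explicit integer seed (R's
Mersenne–Twister, recorded in sidecars); seeded runs are bit-reproducible.

What the generator does **not** emulate: irregular specimen geometry
(axis-aligned boxes and cylinders only — shape does not enter any computed
statistic), polychromatic beam hardening (volumes are synthesized
post-reconstruction), partial-volume chemistry, secondary fluorescence, or
spatially correlated noise. Recovery tests passing on these fixtures
therefore validate the algorithmic chain — scaling, fitting, flooding,
inversion, masking — not robustness to every artifact of real tomograms.

## Problem sizes and tolerances

The shipped tests run single-tissue and two-region fixtures at 128³ voxels
with noise sd 50 HU and blur σ = 1 (Dice ≥ 0.95 against ground truth;
segmented means within twice the configured sd of the generating mean),
watershed-oracle equality on 200 random volumes up to ~10³ voxels, XRF
inversion to <0.1% noiseless, ratio recovery on 96²–256² rasters over 20
seeds at 10% composition noise, and t-test type-I calibration over 2000 null
simulations at n = 20 per group. These sizes were chosen so the entire suite
exercises full-scale volumes while completing in well under a minute of
compute for the segmentation stages.

## Known limitations

* Auto locus detection assumes material modes separated by more than the
  noise width in the intensity histogram; heavily overlapping modes need
  manual boxes.
* The watershed boundary sits on the gradient crest, which under blur lies
  midway through an interface; voxels inside the blurred band are split
  between neighbors, so segment means of thin structures drift toward their
  surroundings.
* Absorption lengths, detector gains and fluorescence yields are
  user-supplied constants; no fundamental-parameters physics, spectral
  fitting or secondary fluorescence.
* Mood's median test is one defensible reading of a "median-based ANOVA";
  Kruskal–Wallis is provided for sensitivity analysis.
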