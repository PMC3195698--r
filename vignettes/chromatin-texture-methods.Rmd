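---
title: "Methods: nuclear chromatin texture, fractal scaling and the
  atypical-precursor classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nuclear chromatin texture, fractal scaling and the atypical-precursor classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyotex)
```

## What the package measures

`karyotex` quantifies the chromatin organisation of segmented cell nuclei
— myeloblasts, promyelocytes and atypical immature myeloid precursors in
bone-marrow smears — and tests, per feature, where the atypical cells sit
on the blast-to-promyelocyte maturation axis. The unit of measurement is
a `nucleus_image`: an 8-bit gray image (0 darkest, 255 brightest), a
single-component binary mask, a pixel calibration (default 0.1 µm/pixel,
the usual sampling of 100x oil-immersion capture), and patient/class
metadata. Every feature reads mask pixels only, so the numbers are
intrinsic to the nucleus and indifferent to the background.

## Morphometry

Area is the mask pixel count (µm² via the calibration). The perimeter is
the length of the 8-connected chain code around the outer boundary
(axial step 1, diagonal √2; holes excluded; a single pixel counts 4).
This convention is exact on polygons — a 5×5 square measures 16 — but
overestimates smooth contours by about 4.7%, so the circularity
4πA/P² of a discrete disk converges to ≈ 0.906 rather than 1; values
above 1 (possible for very small convex shapes, where the chain
underestimates) are clipped. Because "form factor" has no single
convention in karyometry, both circularity (default) and the
second-moment axis ratio are exposed. Gray statistics use the sample SD
(n − 1).

## Co-occurrence texture

`build_glcm()` counts gray-level pairs at displacement d = 1 along the
four directions 0°/45°/90°/135°, both orientations, pooled into one
symmetric matrix — pooling matches the single-value-per-feature
reporting that is standard in this literature, and a pair contributes
only when both pixels are inside the mask. Quantisation keeps all 256
levels by default (configurable to 16–128). The seven features are the
standard functionals of the normalised matrix listed in
`?glcm_features`. Two reporting choices deserve a note:

* *Inertia* and *contrast* are one and the same moment Σ(i−j)²p; the
  field's tables habitually print both rows, so the package returns the
  value under both names rather than inventing a distinction.
* *Diagonal moment* has no unique textbook definition; the package uses
  the first difference moment Σ|i−j|p (dissimilarity). *Energy* is
  reported both normalised (Σp² ≤ 1) and raw (Σ counts², whose scale
  depends on nucleus size); published energy values in the thousands are
  only meaningful on an unnormalised scale.

## Fractal dimension by the blanket method

The gray image is read as a surface (height = gray value). Upper and
lower envelopes start on the surface and are dilated ε = 1…10 times with
the flat 3×3 structuring element plus a unit vertical step, evolving on
mask pixels only. The inter-envelope volume V(ε) grows with ε; for a
smooth surface V(ε) = 2εN exactly (FD = 2), for rough surfaces more
slowly per step.

Two estimators of FD are provided. The default regresses the
*differenced* blanket area A(ε) = (V(ε) − V(ε−1))/2 on a log–log scale
(A ~ ε^(2−FD)), the classical formulation; differencing isolates each
scale's contribution. The alternative (`method = "volume"`) regresses
the cumulative V(ε) directly (V ~ ε^(3−FD)). The cumulative fit is exact
on constructed power-law series, but on genuinely rough surfaces the sum
mixes all scales below ε and compresses the estimate towards 2: in our
calibration on fractional Brownian surfaces (20 seeds, 256×256) the
differenced estimator recovers FD ≈ 2.28/2.53/2.81 for Hurst
H = 0.8/0.5/0.2 (theory: 3 − H = 2.2/2.5/2.8) while the cumulative fit
saturates near 2.34 at H = 0.5 — hence the default. The R² of the fit is
reported as a feature in its own right: uncorrelated noise (e.g.
salt-and-pepper) breaks power-law scaling and lowers R², which is
precisely the texture information goodness-of-fit carries. Estimates
outside [2, 3] (± 0.05) are flagged, never clipped.

The ε range (default 1…10) and 8- vs 4-neighbourhood are configurable;
the fit uses all radii unless `fit_range` narrows it.

## Statistics and the four-outcome rule

The statistical unit is the patient: per-nucleus features are averaged
per (patient, class), requiring at least 30 nuclei per class by default
(configurable, and `strict` turns the exclusion warning into an error).
Patient-level means — not pooled nuclei — are the only reading
consistent with one p-value per feature across a 30-patient cohort.

Three tests are used: the paired t-test for within-patient class
contrasts, Student's pooled-variance t-test between cohorts (Welch
available), and one-way within-subject (repeated-measures) ANOVA for the
global three-class comparison, F = MS_class/MS_error with
df = (2, 2(n−1)), without sphericity correction by default
(Greenhouse–Geisser optionally reported). No multiple-testing adjustment
is applied across the 14 features, matching standard practice in this
setting; users can p-adjust downstream if desired.

Each feature's label is a pure function of three p-values at α = 0.05,
with p = α counting as significant (published usage reports p = 0.05
among significant differences): not-defined if the global test fails or
neither paired test is significant; intermediate if both paired tests
are significant; close-to-promyelocytes if only blast-vs-atypical is;
close-to-blasts if only atypical-vs-promyelocyte is. The rule is total —
an exhaustive pattern enumeration and a 10⁵-triple property test back
this.

## The synthetic generator

Because suitable microscopy data cannot be redistributed, the package
ships a generator whose defaults emulate the study conditions:
nearly-elliptical masks of 110–120 µm² at 0.1 µm/pixel (axis ratio
0.85–0.95, low-order Fourier boundary perturbation), chromatin built
from a fractional Brownian surface (spectral synthesis, power spectrum
f^−(2H+2), theoretical FD = 3 − H) with sparse dark Gaussian clumps
(amplitude ~4 texture SDs, σ ≈ 2–4 px — small deep spots are what
raises the fourth-moment cluster prominence, as calibration showed;
broad shallow blobs merely reshape the histogram), affinely rescaled to
target in-mask mean/SD and clipped to [0, 255]. The blast preset is
rounder and rougher (H = 0.35), the promyelocyte preset more indented
and smoother (H = 0.55), following the published sign pattern of the
maturation contrast. Everything is a pure function of (recipe, seed).

Cohort simulation works at the patient level: class means per feature,
the atypical mean the mixture λ·µ_blast + (1−λ)·µ_pro, a patient random
effect carrying a within-patient correlation ρ (default 0.3) and
residual noise. Defaults are 30 patients, 30 nuclei per class, a two-SD
blast-promyelocyte separation. The generator emulates the *distributional*
structure of real cohorts; it does not render stain color, nucleoli,
or segmentation error, so passing tests demonstrate the pipeline's
correctness and statistical behaviour, not clinical performance on real
smears.

Spectral synthesis is kept for its exact stationarity control; its known
limitation is truncated high-frequency content, which makes the
effective small-lag Hurst exponent slightly higher than nominal at low H
(≈ 0.35 at nominal 0.2). Rank order across H is unaffected, which is
what the recovery tests rely on.

## Numerical and scale choices

* Grayscale conversion of RGB inputs uses ITU-R BT.601 luminance,
  rounded half up — the original capture system's conversion is unknown,
  so absolute gray-level means from other systems are not comparable.
* Degenerate inputs fail loudly rather than silently: empty or
  multi-component masks, pairless co-occurrence configurations,
  zero-variance t-tests, zero within-subject error in the ANOVA, and
  log-log fits with fewer than three points are all errors.
* Test problem sizes are chosen to keep the full suite under a minute at
  one CPU where the property is scale-free (e.g. 128×128 surfaces, 6
  seeds for rank recovery; ~3000-px masks in the end-to-end cohort run),
  while the acceptance suite runs the full 256×256, 20-seed recovery and
  200-replicate cohort simulations.
* Surfaces are mapped to images as mean 128, SD 40 gray levels for the
  recovery experiments; with a bounded 8-bit range this keeps clipping
  below ~0.2% of pixels while leaving enough vertical relief for the
  blanket to resolve roughness.

## Known limitations

Absolute values of the co-occurrence and fractal features depend on
unknowns of the original measurement system (grayscale conversion,
co-occurrence distance/quantisation, blanket ε range), so only signs,
orderings and the classification logic — not absolute published means —
are reproducible targets. The chain-code perimeter bias (+4.7% on smooth
contours) propagates into circularity; comparisons across software
should use the same convention. The repeated-measures ANOVA assumes
sphericity unless the Greenhouse–Geisser option is used.
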