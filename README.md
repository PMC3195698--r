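# karyotex

Nuclear chromatin texture analysis for immature myeloid precursors in
bone-marrow cytology.

## The problem

In myelodysplastic syndromes (MDS), the bone-marrow blast percentage drives
classification and prognosis, but some immature granulocytic precursors
cannot be classified by eye: they have a blast-like cytoplasm (no Golgi
zone) yet nuclear chromatin that looks more mature. `karyotex` quantifies
the nuclear chromatin of such cells and asks, feature by feature, whether
*atypical immature myeloid precursors* sit with myeloblasts, with
promyelocytes, or in between.

The pipeline works on interactively segmented nucleus images (8-bit
grayscale, typically 0.1 µm/pixel) and computes three families of features
per nucleus:

* **morphometry** — area, chain-code perimeter, form factor
  (circularity 4πA/P² or second-moment axis ratio), mean and SD of the
  gray levels;
* **co-occurrence texture** — from the symmetric gray-level co-occurrence
  matrix p(i,j) (distance 1, four directions pooled): Haralick's entropy
  −Σ p log₂ p, inertia/contrast Σ(i−j)²p, local homogeneity
  Σ p/(1+(i−j)²), energy Σp² (and its unnormalised companion),
  diagonal moment Σ|i−j|p, cluster prominence Σ(i+j−µx−µy)⁴p;
* **fractal dimension** — the Minkowski–Bouligand dimension of the
  pseudo-3D intensity surface via the morphological blanket method:
  upper/lower envelopes are dilated ε = 1…10 times inside the mask, the
  blanket area A(ε) = (V(ε)−V(ε−1))/2 scales as ε^(2−FD), and FD and the
  R² of the log–log fit are both reported (R² is itself a texture
  feature).

Per-nucleus features are averaged to one value per patient and cell class
(≥ 30 nuclei per class by default), then compared with paired t-tests
(blast vs atypical, atypical vs promyelocyte), Student's pooled t-tests
(between cohorts) and repeated-measures ANOVA (global, across the three
classes). Each feature is finally labelled by the significance pattern at
α = 0.05:

| global test | blast vs atyp | atyp vs promyelo | label |
|---|---|---|---|
| n.s. | — | — | not defined |
| sig. | n.s. | n.s. | not defined |
| sig. | sig. | sig. | intermediate |
| sig. | sig. | n.s. | close to promyelocytes |
| sig. | n.s. | sig. | close to blasts |

A fully seeded synthetic generator (fractional Brownian chromatin surfaces
with Hurst exponent H, theoretical FD = 3 − H, plus dark Gaussian
chromatin clumps inside Fourier-perturbed elliptical masks; patient
cohorts with a blast↔promyelocyte mixing weight λ for the atypical class)
makes the whole pipeline testable without microscopy data.

## Worked example

```r
library(karyotex)

# one synthetic blast-like nucleus, ~30 um^2 at 0.1 um/pixel
rec <- nucleus_recipe(preset = "blast", mask_area_px = 3000)
nuc <- generate_nucleus(rec, seed = 42, patient_id = "P01",
                        cell_class = "blast", cell_index = 1)
nuc
#> <nucleus_image> 73x73 px, 2999 nucleus pixels, 0.1 um/px
#>   patient P01, class blast, cell 1

round(unlist(nucleus_features(nuc)[c("area_um2", "form_factor", "mean_gray",
                                     "entropy", "fd_minkowski", "fd_r2")]), 4)
#>     area_um2  form_factor    mean_gray      entropy fd_minkowski        fd_r2
#>      29.9900       0.9274     124.9997       8.8218       2.4375       0.9962
```

The nucleus is round (form factor 0.93), hits its target gray level
(mean 125), and its rough preset chromatin (H = 0.35) yields a high
fractal dimension (2.44) with near-power-law scaling (R² = 0.996).

```r
# a simulated 30-patient cohort whose atypical class sits midway (lambda = 0.5)
rec <- cohort_recipe(features = data.frame(
  feature  = c("perimeter", "inertia"),
  mu_blast = c(598, 3.67), mu_pro = c(656, 3.28), sd = c(29, 0.195)),
  lambda = 0.5)
rep <- classify_all(simulate_cohort(rec, seed = 7))
summary(rep)
#> Classification of 2 nuclear features (alpha = 0.05 ):
#>   intermediate             2
#>   close_to_promyelocytes   0
#>   close_to_blasts          0
#>   not_defined              0
```

Both features are placed `intermediate`: with a two-SD class separation
and the atypical mean halfway, both paired tests and the global test are
significant.

For real data, build nuclei with `load_image()` + `load_mask()` +
`nucleus_image()` (or a manifest CSV via `load_manifest()`), then
`analyze_nuclei()` → `aggregate_cohort()` → `classify_all()` /
`compare_cohorts()`.

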