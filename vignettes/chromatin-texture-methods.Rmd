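---
title: "Methods: chromatin texture, blanket fractal dimension, and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin texture, blanket fractal dimension, and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromatex)
```

## The measurement problem

Giemsa-type stains deposit densely in methyl-rich heterochromatin, so the
spatial arrangement of staining intensity across a leukemic nucleus is a
morphological readout of chromatin remodelling. The features implemented
here treat each segmented nucleus as (a) a binary silhouette, (b) a
histogram of 8-bit luminance values, (c) a joint distribution of luminance
pairs at unit distance, and (d) a pseudo-3D height field whose roughness is
summarized by a fractal dimension. All computations are restricted to the
supplied mask: segmentation in this domain is interactive, and the bright
smear background must never leak into texture statistics.

## Conventions that had to be fixed

The source methodology leaves several numerical conventions unstated. Each
choice below is a package decision, fixed once and tested.

**Luminance.** 24-bit RGB converts by Rec.601 weights
(0.299, 0.587, 0.114), the standard for legacy bitmap formats. Inputs
deeper than 8 bits are min–max rescaled to 0–255.

**Perimeter and form factor.** The form factor is 4πA/P² with P measured
on the 8-connected boundary chain code (axial step 1, diagonal step √2).
The raw chain code overestimates smooth digitized perimeters by ~5–6%,
which would push a large disk's circularity down to ~0.91; published
values straddle 1.0, implying the original software corrected for
digitization. We apply the Vossepoel–Smeulders weights (0.980 per axial
step, 1.406 per diagonal step, −0.091 per direction change) plus π for the
half-pixel outward offset of the true outline relative to the pixel-center
chain (offsetting a convex contour outward by t adds 2πt). A digitized
disk of radius 60 then scores 0.99, an axis-aligned square 0.82 ≈ π/4, and
values slightly above 1 remain possible on digitized shapes. The raw chain
length is available via `corner_correction = FALSE`.

**Gray statistics.** Mean and *population* SD (divisor N) over foreground
pixels. At ≥ 5000 pixels per nucleus the N vs N−1 distinction is
negligible, but a convention must be pinned for exact tests.

**GLCM.** Full 256-level dynamics (the published entropies of ≈ 7–8 bits
are only reachable without re-quantization); distance 1; the four
orientations pooled into a single symmetric matrix before normalization
(one value per feature, direction-free); both endpoints of a pair must be
foreground. Entropy defaults to bits (`base = 2`); the original
software's base is unknown and the option is exposed.

**Blanket fractal dimension.** Peleg-style blankets realize the
Minkowski–Bouligand dimension on height fields: with N₄ spatial
neighborhood and unit vertical step,
u₀ = b₀ = z, uₑ = max(uₑ₋₁ + 1, N₄-max uₑ₋₁),
bₑ = min(bₑ₋₁ − 1, N₄-min bₑ₋₁), V(ε) = Σ(uₑ − bₑ) over the mask, and
FD = 2 − slope of log A(ε) on log ε over ε = 1..15. Propagation is
confined to the mask. N₈ is available as an option.

*Normalization.* Two area estimates are classical: the Minkowski sausage
form A(ε) = V(ε)/(2ε) and the incremental form
A(ε) = (V(ε) − V(ε−1))/2. On spectral fBm surfaces (size 256, amplitude
64 gray units, 5 seeds), the sausage form under-recovers the known
dimension 3−H by up to 0.30 at H = 0.3 — the accumulated volume mixes all
scales up to ε, flattening the log–log slope — while the incremental form
recovers 3−H within 0.11 across H ∈ {0.3, 0.5, 0.7, 0.9}. The incremental
form is therefore the default; both are exposed and agree exactly on flat
surfaces.

*Quality of fractality.* The classical presentation rotates the
(log ε, log A) point distribution so the fitted slope lies at 45°, i.e. it
plots real against estimated values, and reports the squared coefficient
of that regression. For an OLS fit this equals cor(log ε, log A)², so R²
is computed directly; `fit_fd(..., rotate45 = TRUE)` performs the literal
real-vs-estimated computation and is asserted equal to 10⁻¹² in the tests.
A perfectly flat surface is defined to have slope 0, FD = 2 and R² = 1
(an ideal — degenerate — fit); any noisy real nucleus stays strictly
below R² = 1.

*Range.* ε runs 1..15 by default. The published nuclei have gray SD ≈
6–11, so the blanket saturates the relief quickly and measured FDs sit
just above 2 (2.08–2.14), exactly as printed; the range is a config knob
recorded in the output.

## The synthetic cohort: what it emulates, what it does not

The generator is the package's stated world: two patient groups with the
published contrasts between FLT3-ITD and classical APL.

| parameter | ITD-like | classical | source |
|---|---|---|---|
| mean gray | 108 | 130 | published group medians |
| gray SD (population) | 6.3 | 8.7 | published group medians |
| Hurst exponent | 0.70 | 0.75 | calibrated, see below |
| clump density (per 1000 px) | 0.5 | 2.0 | calibrated |
| mask shape | bilobed | oval | variant vs classical morphology |
| nuclear area (µm²) | 86.6–115.3 | 83.4–126.9 | published ranges |
| leukocytes ×10⁹/l (log-normal) | median 63 | median 2 | published medians |
| death hazard /month | 0.08 | 0.01 | chosen: ~26% cohort mortality, deaths concentrated in the ITD-like group, as reported |
| censoring | administrative at 41 months | | published follow-up maximum |

Chromatin is synthesized as a spectral fractional Brownian surface
(PSD ∝ f^−(2H+2)) — chosen over midpoint displacement for exact spectral
control and trivial determinism — plus optional dark elliptical
"heterochromatin clumps", then affinely rescaled to the target gray
mean/SD, clipped and quantized, with white (255) background. Each patient
draws from an RNG stream hashed from (seed, patient id), so cohorts are
bit-reproducible and enlarging a cohort leaves existing patients
untouched. Survival is exponential within group — the simplest model
satisfying proportional hazards, which is what the Cox stage assumes.

**Calibration.** Published per-patient medians act as tuning bands. With
8-bit quantization the realized GLCM features are dominated by the gray
SD and the local autocorrelation; Hurst 0.70/0.75 lands the groups at
median FD 2.09 vs 2.12, entropy 7.0 vs 7.8, contrast 1.7 vs 3.1, local
homogeneity 0.60 vs 0.55 — matching the published medians' directions and
(for FD, homogeneity, entropy of the classical group) their printed
bands. A much smoother ITD surface (H ≈ 0.9) would drive FD to ~2.02,
outside the published band, so "smoother chromatin" is realized through
the lower gray SD rather than a higher Hurst exponent.

**Known non-emulations.** Within-patient feature variance is a free
parameter (the study reports only per-patient medians and ranges); gray
histograms are near-Gaussian by construction, so the heavy-tailed
entropy/contrast combination of the printed ITD row (entropy 6.95 *and*
contrast 2.59 at SD 6.3) is not jointly reachable — entropy lands ~7.0
with contrast ~1.7. The published R² group direction (ITD higher) is
*not* reproduced: in this generator R² tracks fit quality of the rougher,
larger-amplitude surfaces and comes out higher for the classical group.
No staining chemistry, no RGB rendering, no overlapping nuclei. A green
pipeline test therefore establishes computational correctness and
direction-level fidelity, not biological realism of individual nuclei.

## Statistics

* **Mann–Whitney:** U with midranks; exact two-sided p (twice the smaller
  tail of the exact U law) when n ≤ 16 without ties, else normal
  approximation with tie and continuity correction.
* **Spearman:** Pearson correlation of midranks; exact permutation p for
  n ≤ 8 (full n! enumeration), else the t approximation with n−2 df.
* **Exact binomial CI:** Clopper–Pearson by bisection on the binomial
  tails to 10⁻¹⁰ (boundary rules: lower 0 at 0 successes, upper 1 at n).
  This method reproduces the published intervals for 2/19 and 4/19 to all
  printed decimals. The printed interval for 3/19 (0.0478–0.384) is *not*
  Clopper–Pearson (which gives 0.0338–0.3958) and is excluded from
  acceptance as a probable transcription or method mix-up in the source.
* **Cox regression:** single-covariate Breslow partial likelihood,
  Newton–Raphson (tolerance 10⁻⁸, max 50 iterations, step damping);
  Wald p. Monotone likelihood (|B| drifting past 50) is flagged
  `converged = FALSE` instead of silently diverging. The stratified
  variant multiplies within-stratum Breslow terms; strata without events
  contribute nothing, and a covariate constant within every stratum is a
  validation error. Breslow (not Efron) matches the era-typical software
  defaults. Two-sided p throughout; no multiple-testing correction, as in
  the source analysis — consumers see raw p-values.
* **Aggregation:** per-patient medians (even counts: mean of central
  order statistics), minimum 100 nuclei per patient by default,
  configurable downward for small test cohorts.

## Numerical and degenerate-input choices

* Bisection rather than `qbeta` for the CI (the contract is the tail
  equation; Beta quantiles serve as the independent test oracle).
* GLCM of an image with no valid intra-mask pairs is an error, not an
  empty matrix.
* Blanket series on a single-pixel mask degenerates to the bare cone
  (A(ε) = 1), and V(ε) − V(ε−1) ≥ 2N always — both asserted as tests.
* Masks are binarized at 128 on the 0–255 scale; empty masks and shape
  mismatches are validation errors naming the offending file.
* All file outputs (ASCII PGM, CSV, JSON) are written deterministically;
  the pipeline invariant "same seed ⇒ byte-identical tree" is tested.

## Limitations

Absolute FD values from blanket methods are convention-dependent (ε range,
neighborhood, normalization); cross-study comparability requires matching
conventions, which unpublished in-house software precludes. Acceptance
therefore rests on mathematical oracles (flat surfaces, fBm with known
dimension, brute-force dilation) plus the published plausibility bands.
The form-factor digitization correction is exact only in the smooth-convex
limit. The synthetic generator supports directional and calibration
claims, not distributional realism of clinical material.
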