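# chromatex

Nuclear chromatin texture and morphometry for leukemia cytology.

In acute promyelocytic leukemia (APL), clinically distinct presentations —
notably blasts carrying the FLT3 internal tandem duplication (FLT3-ITD) —
show subtly different nuclear chromatin in routine May-Grünwald-Giemsa
smears: smoother, more homogeneously distributed heterochromatin that a
trained observer cannot reliably grade by eye. `chromatex` quantifies that
pattern per nucleus and runs the cohort-level statistics used to relate it
to molecular status and survival.

## What it computes

For each interactively segmented nucleus (8-bit grayscale image + binary
mask + µm/pixel calibration):

* **Geometric morphometry** — nuclear area (µm²), form factor
  (circularity, 4πA/P² with a digitization-corrected 8-connected chain-code
  perimeter), within-mask gray-level mean and population SD.
* **Gray-level co-occurrence matrix (GLCM) texture** — one symmetric
  256-level matrix pooled over the four unit-distance orientations,
  restricted to pixel pairs lying entirely inside the mask, yielding

  - entropy: −Σ p·log₂ p (bits)
  - contrast: Σ (i−j)²·p
  - local homogeneity: Σ p/(1+(i−j)²)
  - cluster prominence: Σ (i+j−µx−µy)⁴·p

* **Minkowski–Bouligand fractal dimension** of the pseudo-3D surface
  (z = gray level), by blanket dilation: upper/lower envelopes grow by
  u_ε = max(u_{ε−1}+1, N₄-max), the blanket volume V(ε) = Σ(u−b) gives
  surface area estimates A(ε), and FD = 2 − slope of log A vs log ε.
  The quality of fractality R² (1.0 for an ideal fractal, <1 for real
  chromatin) comes from the same log–log fit.

Cohort statistics: per-patient feature medians, two-sided Mann–Whitney
group comparisons, Spearman rank correlations, exact (Clopper–Pearson)
binomial confidence intervals, and univariate plus stratified Cox
proportional-hazards regression (Breslow ties) — stratification by
FLT3-ITD status is how the source study showed texture features lose
their prognostic value once mutation status is held fixed.

A seeded synthetic-cohort generator (fractional Brownian chromatin
surfaces with known fractal dimension 3−H, oval/bilobed masks,
exponential survival with administrative censoring) makes every stage
testable without clinical data.

## Worked example

```r
library(chromatex)

cfg <- generator_config(seed = 42, n_patients_per_group = 4,
                        nuclei_per_patient = 10)   # demo-sized cohort
b <- generate_cohort(cfg)

feats <- do.call(rbind, lapply(b$nuclei, function(n)
  cbind(data.frame(patient_id = n$patient_id),
        as.data.frame(as.list(nucleus_features(n))))))

cohort_report(feats, b$patients, grouping = "flt3_itd", min_nuclei = 10)
```

prints (demo run with small 20–30 µm² nuclei for speed; abridged):

```
Group comparison by 'flt3_itd' (0 vs 1), Mann-Whitney p:
            feature median_g1 median_g2       p
          mean_gray 1.295e+02 1.082e+02 0.02857
            sd_gray 8.704e+00 6.306e+00 0.02857
            entropy 8.258e+00 7.327e+00 0.02857
           contrast 5.472e+00 2.753e+00 0.02857
  local_homogeneity 4.048e-01 5.074e-01 0.02857
                 fd 2.258e+00 2.165e+00 0.02857
    leukocyte_count 1.611e+00 6.267e+01 0.02857

Spearman correlation with leukocyte count:
            feature    rho        p
            sd_gray -0.976 0.000397
            entropy -0.857 0.010714
                 fd -0.833 0.015377
```

The ITD-like group shows lower gray-level SD, entropy, contrast and
fractal dimension but higher local homogeneity, and the leukocyte count
correlates negatively with SD, contrast and FD — the direction of every
published group contrast. (Feature magnitudes depend on nuclear area; the
full-size default configuration, ~85–127 µm² nuclei at 0.1 µm/px,
reproduces the published per-patient median bands, e.g. FD 2.08–2.14.)
The stratification phenomenon:

```r
d <- merge(aggregate_patient(feats, 10), b$patients)
cox_univariate(d, "entropy")
#> <cox entropy: B = -2.176, p = 0.07837>
cox_stratified(d, "entropy", "flt3_itd")
#> <cox (stratified) entropy: B = +7.314, p = 0.4481>
```

and the exact binomial CI that the study reports for 2 FLT3-ITD cases
among 19 patients:

```r
clopper_pearson_ci(2, 19)
#> <2/19 = 10.5%; 95% exact CI 0.0130 - 0.3314>
```

## Command line

```sh
chromatex simulate --config cfg.json --out cohort/
chromatex features --manifest cohort/manifest.csv --calibration 0.1 --out features.csv
chromatex stats --features features.csv --patients cohort/patients.csv \
          --group flt3_itd --strata flt3_itd --out reports/
```

(`inst/cli/chromatex`; all randomness flows through the single config seed,
and reruns are byte-identical.)

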