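# hsisas

Quantitative assessment of rheumatoid-arthritis treatment response from
short-wave infrared (SWIR, 900–1700 nm) hyperspectral wrist images, for
researchers in biomedical optical imaging and quantitative rheumatology.

Inflammation changes periarticular water content, scattering and
microstructure, which shifts tissue reflectance in the SWIR — water
absorbs near 970, 1190 and 1450 nm, and the hydration-sensitive region
near 1250 nm moves with treatment.  `hsisas` turns paired
(pre/post-treatment) hyperspectral cubes into per-wrist **soft abundance
scores** that quantify how closely each wrist spectrum matches a
post-treatment reference pattern, and compares them with clinical
indices (DAS28, ESR, CRP) and power-Doppler ultrasound.

## The statistic at the core

For a pixel spectrum `r` (1×L), a target signature `d` (the mean
post-treatment wrist spectrum) and a spectral correlation matrix `R`
(L×L), the constrained-energy-minimization (CEM) score is

    δ(r) = (r R⁻¹ d) / (dᵀ R⁻¹ d)

which has unit response at the target (δ(d) = 1), is linear in `r`, and
minimizes the mean squared output over the background described by `R`.
The **intra**-subject score uses one subject's correlation structure and
target; the **inter**-subject score uses the pooled cohort's.  `R` is
symmetrized and ridge-regularized before inversion (recorded λ).
Wrist-level scalars (pixel means of the score maps) feed a
nonparametric layer: median/IQR summaries, exact Wilcoxon signed-rank
pre/post tests, and Spearman correlations over improvement-oriented
deltas.

The pipeline stages are: flat-field reflectance calibration from
white/dark references → 1303/1453 nm band-ratio + Otsu wrist
segmentation → 100-row wrist ROI at an operator wrist row → correlation
estimation → CEM scoring → cohort statistics → figures (mean ±1 SD
spectra, red→green abundance maps, intra/inter projection).  A fully
synthetic SWIR cohort generator (hand phantom, water absorption bands,
treatment-modulated 1250-nm feature, coupled clinical covariates) makes
every stage testable without clinical data.

## Worked example

```r
library(hsisas)
co  <- generate_cohort(m = 4, scene = phantom_scene(rows = 64L, cols = 48L,
                                                    L = 32L), seed = 42)
res <- run_pipeline(co, "demo_out")
print(res$report, digits = 2)
```

```
Pre/post summary (median (q1, q3), Wilcoxon signed-rank p):
      variable n_pairs pre_median pre_q1 pre_q3 post_median post_q1 post_q3 p_value
         das28       4      4.310  4.095  4.364        3.78    3.36    4.12  0.2500
  esr_mm_per_h       8     30.150 28.199 31.960       11.36    8.76   18.50  0.0312
 crp_mg_per_dl       8      1.092  0.434  1.913        0.00    0.00    0.36  0.0078
  intra_hsisas       8      0.064  0.035  0.084        1.00    1.00    1.00  0.0078
  inter_hsisas       8      0.136  0.131  0.137        0.88    0.75    1.10  0.0078
```

Reading it: the synthetic treatment raised both abundance scores from
near 0 toward 1 (post spectra match the post-treatment reference;
exact signed-rank p = 0.0078 at n = 8 wrists), ESR/CRP improved, and
DAS28 (patient-level, n = 4 pairs) trends down but cannot reach
significance at that n.  The accompanying Spearman block shows
ΔIntra and ΔInter strongly correlated with each other, and
`plot_projection(res$records)` separates the pre and post clusters
(separation statistic 7.9 on this run).  Columns `corr_mode`,
`reducer` and the ridge λ are carried in `res$records` and
`demo_out/meta.txt`; no setting is silent.

## Command line

```sh
inst/cli/hsisas simulate --m 11 --effect 0.1 --seed 42 --out simdata/
inst/cli/hsisas calibrate --raw scan.bsq --white white.bsq --dark dark.bsq --out refl.bsq
inst/cli/hsisas segment --cube refl.bsq --wrist-row 300 --extension 100 --out roi
inst/cli/hsisas pdus --image frame.ppm --roi synovium.csv --mode reddom --threshold auto
```

Cubes are ENVI-style (text header + flat little-endian binary, BSQ or
BIL); raster interchange uses ASCII PNM (the environment has no PNG
codec).
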