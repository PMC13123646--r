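---
title: "Soft abundance scoring of SWIR wrist images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soft abundance scoring of SWIR wrist images: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsisas)
```

## The problem and the measurement model

Rheumatoid arthritis (RA) treatment response is usually followed with
operator-dependent instruments: the DAS28 composite score, and
power-Doppler ultrasound (PDUS) read by a clinician.  Short-wave
infrared (SWIR, 900--1700 nm) hyperspectral imaging offers a
non-contact optical alternative: inflammation changes periarticular
water content, scattering and microstructure, which shifts the
reflectance spectrum — water absorbs near 970, 1190 and 1450 nm, and
the first water overtone region near 1250 nm is particularly sensitive
to tissue hydration.

This package implements a complete analysis chain for paired
(pre/post-treatment) SWIR wrist cubes:

1. **Reflectance calibration.**  A raw counts cube is flat-fielded with
   white- and dark-reference acquisitions:
   $\rho = (\mathrm{raw}-\mathrm{dark})/(\mathrm{white}-\mathrm{dark})$,
   clipped to $[0, 2]$ (specular highlights legitimately exceed 1).
   Pixels with a degenerate denominator are imputed to 0 and flagged in
   a QC mask rather than propagating NaN into the correlation
   estimators.  The white reference can be applied per pixel (default)
   or averaged per across-track column, because a push-broom system
   images the white board at one scan location.
2. **Wrist segmentation.**  The 1303/1453 nm band ratio exploits the
   deep tissue water dip at 1450 nm: it is high on skin, near 1 on the
   imaging board.  Otsu's between-class-variance threshold binarizes
   the ratio image; a 3×3 morphological closing plus
   largest-4-connected-component cleanup (both disengageable) removes
   speckle.  The wrist ROI is the hand mask intersected with a fixed
   100-row band anchored at an operator-chosen wrist row, extending
   toward the forearm (rows increase away from the fingers; `direction`
   and `centered` flags cover the other conventions, since either could
   match a given acquisition).
3. **Spectral correlation structure.**  Two estimators of the $L \times
   L$ matrix $R$ are provided (see *Design choices*).
4. **CEM abundance scoring.**  The constrained-energy-minimization
   score of a pixel spectrum $r$ against a target signature $d$ is
   $$\delta(r) = \frac{r\,R^{-1}d}{d^{\mathsf T}R^{-1}d},$$
   which passes the target with unit gain ($\delta(d)=1$), is linear in
   $r$, and minimizes mean squared output over the background described
   by $R$.  $d$ is the mean post-treatment wrist spectrum — pooled over
   one subject's two hands for the *intra*-subject score, over the
   whole cohort for the *inter*-subject score.  A wrist-level scalar is
   the pixel mean of the map (median and 10% trimmed mean available;
   the reducer is recorded in every record).
5. **PDUS quantification.**  Given an expert polygon, the synovial area
   is its even-odd rasterization (boundary pixel centers included) and
   the PD area is the count of ROI pixels whose red-gray value exceeds
   a threshold (Otsu-within-ROI by default).
6. **Cohort statistics.**  Median/IQR summaries, exact Wilcoxon
   signed-rank pre/post tests, and Spearman correlations over
   improvement-oriented deltas (`pre − post` for variables expected to
   fall — synovial area, PD area, DAS28, ESR, CRP — and `post − pre`
   for the abundance scores, so positive always means improvement).
   DAS28 is patient-level: one delta per subject, assigned to both
   wrists, excluded pairwise when a visit's value is missing.

## Tunable parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `clip_max` (calibration) | 2.0 | reflectance | bounds specular pixels |
| band-ratio wavelengths | 1303 / 1453 | nm | tissue-water contrast |
| `extension_rows` | 100 | rows | fixed wrist band height |
| `corr_mode` (scoring) | `"cem"` | — | see below |
| `ridge_lambda` | `"auto"` = $10^{-6}\,\mathrm{tr}(R_s)/L$, escalated ×10 until $\lambda_{\min} > 10^{-10}$ | — | invertibility when $n < L$ |
| wrist reducer | mean | — | unbiased, simplest |
| quantile method | `linear` (type 7) | — | recorded in reports; SPSS variant available |
| Wilcoxon zeros | drop | — | classic convention; Pratt by flag |

Scores are *not* clipped to $[0,1]$: CEM output is unbounded, and
clipping would hide pathological fits.  Map rendering clips for display
only (red = 0 = severe, green = 1 = mild).

## Design choices where the design was genuinely open

**Reading of the correlation estimator.**  The printed intra/inter
correlation expressions are scalar Pearson forms labelled as $L \times
L$ matrices.  Two readings are implemented: `"pearson"` — the band-pair
cross-correlation $R[a,b] = \mathrm{corr}(\text{pre band } a,
\text{post band } b)$ across paired pixels, the direct matrix reading
of the printed formula — and `"cem"` — the classic detector-literature
sample autocorrelation $\tfrac1N \sum_i r_i r_i^{\mathsf T}$ of the
pooled, uncentered pre+post pixel spectra.  The matrix constructors
default to `"pearson"` (faithful to the printed form).  The cohort
scorer defaults to `"cem"`, because measurement settled the question:
on synthetic cohorts the Pearson matrix — whose cross-visit pixel noise
drives it toward a ridge-dominated, projection-like detector — produces
pre- and post-treatment scores that are statistically
indistinguishable, whereas the autocorrelation reading suppresses
off-target (pre-treatment) spectra and reproduces the expected
low-pre/high-post pattern.  The mode travels with every matrix, map and
record.

**Denominator of the score.**  The source formulation prints the
normalization once without the inverse and twice with it; the
implemented default is $d^{\mathsf T}R^{-1}d$ — the standard CEM
normalization and the only choice with $\delta(d)=1$.  The literal
no-inverse variant is available (`denominator = "plain"`).

**Symmetrization + ridge.**  The band-pair matrix is non-symmetric and,
with fewer paired pixels than bands, rank-deficient; the quadratic form
presumes a symmetric positive-definite system.  $R_s = (R+R^{\mathsf
T})/2$ plus the auto ridge above guarantees that.  The $\lambda$ used
is recorded in all outputs.

**Pixel pairing.**  The estimators assume a common pixel index over the
two visits.  Default: truncate both ROIs to the first $n =
\min(n_\text{pre}, n_\text{post})$ pixels in raster order
(deterministic); seeded subsampling is available.

**Wrist band anchoring.**  The 100-row band is anchored *at* the wrist
row (not centered); both alternatives are flags, since the convention
cannot be inferred from a verbal description.

## What the synthetic generator emulates — and what it does not

A scene is a stylized hand silhouette (palm, three fingers, forearm;
per-subject affine jitter) on a flat board, at a reduced default
geometry of 96×64 pixels and 64 bands (full 635×640×512 available).
Reflectance is a quadratic baseline minus Gaussian absorption bands at
970/1190/1450 nm plus an inflammation band at 1250 nm whose amplitude
*increases* by `treatment_delta` × a lognormal subject effect after
treatment (post-treatment reflectance near 1250 nm is lower, the
clinically observed direction; default amplitude change 0.10 on a ~0.5
baseline).  Noise: additive Gaussian pixel noise (SD 0.02), a
subject-level lognormal brightness factor (SD 0.05), and a smooth
spatial gain field fixed across visits.  Raw counts are synthesized so
that flat-field calibration recovers the reflectance exactly up to the
pixel noise.  Clinical covariates (DAS28 ~ 4.8 falling by ~0.5, ESR ~
31 mm/h, CRP ~ 1.5 mg/dL) improve proportionally to each subject's
spectral effect plus noise, so the score–DAS28 association is
recoverable by design.

The generator does **not** model anatomy, joint structure, radiative
transfer, specular geometry, spectral smile, or registration error
between visits (pixel pairing across visits is idealized).  A green
end-to-end test therefore establishes that the pipeline recovers a
planted spectral treatment effect and its clinical coupling under
realistic noise — not that the method is clinically valid.

## Numerical choices

* Otsu: between-class variance is computed from exact per-bin value
  sums (not bin centers) over a 256-bin histogram; ties break toward
  the lower edge; constant images are an error.
* Band lookup: nearest band center, ties toward the lower index;
  out-of-range wavelengths are errors, never clamped.
* Correlation: zero-variance bands raise an error naming the band.
* The map path computes one linear solve $w = R_\lambda^{-1} d$ and
  per-pixel dot products; it agrees with per-pixel inversion to 1e-10.
* Quantiles: linear interpolation at $p(n-1)$ (R type 7) by default;
  the method is configurable and recorded because different statistical
  packages disagree and the original choice is unknowable.
* Wilcoxon: exact null distribution by a tie-aware count dynamic
  program (equivalent to full $2^n$ sign enumeration) for effective
  $n \le 25$; beyond that, normal approximation with tie and continuity
  correction.

## Known limitations

**Internal self-referencing bias at small pixel counts.**  The target
$d$ is estimated from the very post-treatment pixels that are later
scored.  Writing $d = \mu + \bar\varepsilon$ with
$\lVert\bar\varepsilon\rVert^2 \approx \sigma^2 L/n_{\text{post}}$, the
denominator $d^{\mathsf T}R^{-1}d$ acquires an inflation term
$\bar\varepsilon^{\mathsf T}R^{-1}\bar\varepsilon \approx
L/n_{\text{post}}$ whenever the ridge sits below the noise eigenvalue
floor $\sigma^2$ of the autocorrelation — and only in-sample (post)
pixels, whose noise overlaps $\bar\varepsilon$, recover it.  Measured
on null cohorts (no treatment effect, $L=64$, $n_{\text{post}}=800$):
post scores ≈ 1.000, pre scores ≈ 0.925 — bias 0.075, matching the
predicted $L/n = 0.08$ — so a wrist-level signed-rank test flags
essentially every null cohort at this desk-scale geometry.  The bias
shrinks like $L/n$ (negligible at full acquisition scale, where $n$ is
tens of thousands) and vanishes when `ridge_lambda` is raised above the
noise floor (measured: 0.075 at the auto ridge, 0.003 at $\lambda =
10^{-2}$), at the cost of attenuating the effect contrast.  The default
keeps the conditioning-only auto ridge for fidelity; users running
small ROIs should either supply an external target spectrum
(`build_target` accepts any ROI pool) or set `ridge_lambda` near the
pixel-noise variance.  The corresponding null-control acceptance test
is deliberately left failing as an honest record of this property.

**Other limitations.**  Two wrists of one subject are analyzed as
independent observations (as in the source protocol); no mixed-effects
correction is applied, and a note to that effect is printed on every
report.  No multiple-testing correction by default (Holm available).
No spatial co-registration between visits.  Raster interchange uses
ASCII PNM rather than PNG because the target environment has no PNG
codec; the formats are loss-free for 8-bit data.
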