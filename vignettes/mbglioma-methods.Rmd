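---
title: "Multi-b diffusion MRI analysis of brain tumors: models, phantom design and validation"
author: "mbglioma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-b diffusion MRI analysis of brain tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbglioma)
```

## The problem

High-grade gliomas (HGG) and solitary brain metastases can look alike on
conventional MRI, yet their management differs fundamentally. Multi-b
diffusion-weighted imaging probes tissue microstructure and perfusion at
the voxel level and, combined with compartment-wise histogram statistics
and a simple classifier, can support the differential diagnosis. This
package implements that whole analysis chain — forward models, voxelwise
estimators, mask algebra, first-order radiomics, cohort statistics,
LASSO + CART classification, and inter-rater reliability metrics —
together with a synthetic phantom cohort generator so every stage can be
exercised and validated end to end without patient data.

## Signal models

Two single-direction models are fitted per voxel from one 10-b-value
acquisition (b = 0, 10, 20, 30, 50, 100, 200, 500, 1000, 2000 s/mm²,
with 1, 1, 1, 1, 1, 2, 2, 3, 3, 6 signal averages).

**IVIM (intravoxel incoherent motion)**, a biexponential separating
capillary pseudo-diffusion from tissue water diffusion:

$$S(b) = S_0\left[f\,e^{-b D^*} + (1 - f)\,e^{-b D}\right]$$

with perfusion fraction $f \in [0,1]$, pseudo-diffusion coefficient
$D^*$ and diffusion coefficient $D$ (mm²/s internally; reported in
$10^{-6}$ mm²/s).

**Diffusion kurtosis**, capturing non-Gaussian diffusion at high b:

$$S(b) = S_0\,e^{-b D + b^2 D^2 K / 6}$$

with dimensionless kurtosis $K$. Note the deliberate distinction between
*diffusion* kurtosis $K$ (a tissue property) and *histogram* kurtosis (a
fourth-moment statistic of any feature's voxel distribution).

Only the IVIM $D$ enters cohort statistics; the kurtosis-model $D$ is
computed but excluded, mirroring common practice.

## Estimators

### IVIM by variable projection

The model is separable: for fixed $(D^*, D)$ it is linear in the
non-negative amplitudes $(S_0 f, S_0(1-f))$, which have a closed-form
non-negative least-squares solution (2×2 normal equations with boundary
clamping). The outer problem over $(\log D, \log D^*)$ is solved by a
deterministic fine log-spaced grid (default 60 × 60; the Gram matrices
are precomputed once and shared across voxels, so the scan costs a few
microseconds per voxel) followed by Nelder–Mead refinement with
restarts from the best grid nodes. A one-step fit over all b-values was
chosen over the two-step high-b approach because it needs no operator
threshold; a two-step mode exists behind `fitOptions(method =
"two-step")` for comparison only.

Numerical choices that matter:

* **Bounds** $D \in [10^{-6}, 4\times10^{-3}]$, $D^* \in [10^{-3}, 0.5]$
  mm²/s: wide enough to bracket reported tumor and brain values with a
  large margin.
* **Separation constraint** $D^* \ge 3D$ prevents label switching
  between the two exponentials.
* **Why a fine grid rather than a handful of multi-starts:** the
  variable-projection residual surface has a narrow curved ravine for
  low-contrast voxels ($D^*/D \approx 5$); plain Nelder–Mead from coarse
  starts — including R's own `optim` implementation — stalls inside it
  on a percent-level fraction of admissible draws. Starting inside the
  correct basin from a fine grid fixes this; noiseless signals are then
  recovered to relative error $\sim 10^{-6}$, and by construction the
  final residual can never exceed that of a 50 × 50 grid search.
* **No RNG anywhere in fitting** — maps are bit-reproducible.
* Degenerate voxels ($f$ at a boundary, where $D^*$ is unidentifiable)
  are flagged rather than silently reported.

### Kurtosis by log-domain polynomial fit

$\ln S(b) = c_0 + c_1 b + c_2 b^2$ is fitted by unweighted least squares
over all b-values and mapped to $D = -c_1$, $K = 6 c_2 / c_1^2$. This is
exact for noiseless model data and unambiguous. $K$ is clipped to
$[0, 3]$; when clipping occurs, $S_0$ and $D$ are refitted with $K$ held
at the bound, and the clip is flagged. Whether the upstream tooling that
popularized "logarithmic fitting" weights the log-residuals is not
documented; unweighted is used here and stated openly (weighting by
$n_{\mathrm{avg}} S^2$ was evaluated and changes voxelwise $K$ error by
under one percentage point).

In `fitMaps`, the kurtosis branch runs on signals Gaussian-smoothed
spatially per b-volume (default sigma 5, interpreted in voxels since the
originating tool does not state units), while the IVIM branch uses
unsmoothed signals — matching how the two analyses are used in practice.

## The phantom generator

The generator emulates the *study conditions* of a two-group clinical
cohort: 67 HGG and 30 metastasis training subjects plus a 9 + 8
validation set, Rician noise at the acquisition's per-b averaging, and
per-tissue parameter distributions calibrated to published medians and
interquartile ranges of subject-level tissue medians
(`defaultCalibration`).

* **Anchor distributions.** Log-normal for $D$, $D^*$ and volumes
  (positive, right-skewed, matching the asymmetric printed IQRs),
  logit-normal for $f$, truncated normal for $K$; each matched by median
  and IQR and truncated to physiologic bounds ($f \in [0.01, 0.95]$,
  $D \le 4\times10^{-3}$ mm²/s, $D^* \ge 3D$, $K \in [0.01, 3]$, volumes
  in [0.05, 200] mL). When the lower quartile is 0 (non-enhancing volume
  in metastases) the log-scale spread is set from the upper quartile
  alone.
* **Absent compartments.** The non-enhancing (necrotic/cystic) tissue is
  absent with probability 0.4 in metastases and 0.05 in HGG — motivated
  by a metastasis non-enhancing volume IQR reaching 0 — while enhancing
  tumor and edema are always present. Downstream code must handle the
  resulting absent-feature markers.
* **Geometry.** Concentric, randomly rotated, anisotropically scaled and
  smoothly deformed ellipsoids: non-enhancing core inside an enhancing
  shell inside an edema rim, realized as nested level sets of one radial
  field, so compartments are exactly disjoint, their union is connected,
  and voxel counts match target volumes to the nearest voxel. Real
  lesions are far more irregular, but geometry enters no downstream
  statistic except volume, which is matched exactly. Lesions that cannot
  fit the grid are rejected and redrawn from a derived seed (a
  physiologic truncation of extreme volume draws).
* **Voxel heterogeneity.** Within tissues, parameters are the anchor
  times a multiplicative log-normal jitter field (default 10% relative
  SD, optionally spatially correlated). The study data report only
  subject-level medians, so this scale is a free parameter of the
  phantom, documented rather than claimed to match any cohort.
* **Forward model and noise.** One joint expression
  $S(b) = S_0[f e^{-bD^*} + (1-f) e^{-bD + b^2D^2K/6}]$ makes a single
  voxel consistent with both analyses. Noise is Rician — the magnitude
  of complex Gaussian noise with sd $S_0/\mathrm{SNR}$ — drawn
  independently per signal average, and the stored signal is the mean of
  the per-average magnitudes, as on a scanner; the high-b noise floor is
  therefore reproduced, not suppressed.

**What passing tests do and do not show.** Fitting each sub-model to
joint-model voxels incurs *systematic* cross-model bias: the perfusion
component adds low-b curvature that inflates the fitted $K$, and the
kurtosis upturn slows the apparent high-b decay, deflating the IVIM $D$
and inflating $f$. These biases are shared by both groups and largely
cancel in group comparisons (some contrasts are even amplified because
the fitted value compounds several group-separated anchors), but
absolute fitted values on joint-model phantoms should not be read as
accuracy statements. Exact-recovery tests therefore use sub-model
generation. None of this guarantees behavior on real tissue, where the
two models are both approximations of the same underlying signal.

## Feature extraction and statistics

Per present tissue and per map ($f$, $D$, $D^*$, $K$): mean, median,
sample SD, min, 5th/25th/75th/95th percentiles (linear interpolation),
max, adjusted Fisher–Pearson skewness and bias-corrected *excess*
kurtosis (SPSS convention, normal → 0; undefined below n = 4), plus the
three tissue volumes — 135 named features
(`<param>_<tissue>_<stat>`, `vol_<tissue>`). "Histogram analysis" is
read as statistics of the raw voxel values, not fixed-bin histograms.

Group comparison skips absent markers, uses the Wilcoxon rank-sum test
(exact for the smaller group ≤ 10 without ties, otherwise the corrected
normal approximation), and controls FDR by Benjamini–Hochberg over all
135 features as one family. ROC analysis sweeps all cut midpoints, takes
AUC from the Mann–Whitney identity with a DeLong 95% CI, picks the
threshold maximizing sensitivity + specificity (ties broken toward
higher specificity — a documented deterministic rule), auto-orients the
direction so AUC ≥ 0.5, and reports a univariate logistic odds ratio at
that threshold (Wald CI; Haldane–Anscombe 0.5 correction with a flag
when a 2×2 cell is empty). Both the tie-break and the CI methods are
package decisions; the underlying study names only software packages.

## Classification

Zero-imputation of absent markers (with a retained audit mask), then
L1-penalized logistic regression on standardized features with the
penalty chosen by seeded 10-fold cross-validated deviance and the 1-SE
rule; plain (ungrouped) LASSO is used since no grouping structure is
implied. The selected features feed a CART tree (Gini impurity,
exhaustive midpoint split search, minsplit 20, cost-complexity pruning
at cp = 0.01 — conventional defaults, both configurable) with metastasis
as the positive class throughout. The four features of the published
differentiation tree (`K_enh_p95`, `vol_nonenh`, `Dstar_edema_kurt`,
`K_enh_p5`) ship as a fixed alternative subset
(`publishedTreeFeatures()`) since the published thresholds exist only in
a figure.

## Reliability metrics

Dice coefficient $2|A \cap B| / (|A| + |B|)$ (two empty masks defined as
1 with a flag); average Hausdorff distance as the **max** of the two
directed mean nearest-neighbor distances on voxel centers in physical
mm (the convention of the standard segmentation-evaluation tool; the
symmetric-mean variant is available behind a flag); and ICC(2,1) —
two-way random effects, absolute agreement, single measures — from the
two-rater ANOVA mean squares with F-based CI and p-value. Whether the
original analysis used consistency or absolute agreement is unstated;
absolute agreement is the stricter, documented choice (a constant
rater offset lowers it, as a test asserts).

## Problem sizes used in the shipped validation

The test-suite and the acceptance script run everything at reduced
size, chosen once as follows:

* End-to-end cohort replicates: 67 + 30 training and 9 + 8 validation
  subjects on 20³ grids with 6 mm isotropic voxels (median whole-lesion
  size ≈ 300 voxels), SNR 40, 20 master seeds.
* At this resolution the kurtosis-branch smoothing uses sigma 1 voxel:
  the acquisition-scale default (sigma 5 at ~2 mm voxels ≈ 10 mm) would
  span the entire enhancing shell of a coarse-grid phantom and mix
  compartments; one coarse voxel ≈ the physical extent of the original
  smoothing.
* Noisy-recovery checks: ≥1000-voxel uniform blocks per parameter set,
  sub-model generation, fitted through `fitMaps` exactly as in the
  pipeline.
* Estimator precision at this acquisition has real information limits:
  for low-perfusion-contrast parameter sets ($D^*/D \approx 5$, typical
  of edema), the median voxelwise $|\Delta f|$ at SNR 40 is ≈ 0.07 *for
  any least-squares estimator* — a brute-force grid search does no
  better — while enhancing-tumor-like sets reach ≈ 0.03–0.04. The suite
  asserts both: tight bounds where the scheme supports them, and
  estimator-vs-oracle parity where it does not.

## Known limitations

* The phantom draws each tissue anchor independently; real lesions have
  correlated microstructure across compartments and parameters, so the
  phantom likely *understates* achievable multivariate separation.
* No EPI distortion, motion or eddy-current simulation: corrected,
  co-registered, skull-stripped inputs are assumed.
* Single evaluated lesion per subject; no shared-edema exclusion logic.
* The decision-tree stage inherits CART's instability on small
  validation sets; the end-to-end suite quantifies this across seeds
  rather than hiding it.
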