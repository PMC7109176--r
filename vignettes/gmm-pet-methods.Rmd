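---
title: "GMM–PET lesion segmentation: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GMM–PET lesion segmentation: models, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petgmm)
```

`petgmm` extracts treatment-response biomarkers (tumor area, mean apparent
diffusion coefficient) from co-registered PET/MRI slices by segmenting the
lesion on the PET standardized-uptake-value (SUV) map with a three-class
Gaussian mixture, then transferring the mask to the ADC map. This vignette
is the package's own account of the models it implements, the parameters
that matter, the synthetic data it validates against, and the choices made
where the design was genuinely open.

## Quantitative maps

**SUV.** `compute_suv()` applies the body-weight convention:
`SUV = C · w / D` with concentration `C` in kBq/mL, body weight `w` in kg
and injected dose `D` in MBq. Under the emulated protocol (4 MBq per kg)
tissue at the whole-body mean concentration has SUV 1. Tracer decay
correction to injection time is assumed to have been applied upstream by
the scanner; the package deliberately implements only the weight/dose
normalization.

**ADC.** `fit_adc()` inverts the mono-exponential decay
`S_b = S_0 · exp(−b · ADC)` per voxel by ordinary least squares of
`log S_b` on `b`. The fit uses only b ≥ `b_min` (default 200 s/mm²):
capillary pseudo-diffusion decays so fast that the low-b points are
contaminated by perfusion, and dropping them yields a perfusion-insensitive
tissue diffusivity. With the emulated acquisition (b = 0, 50, 120, 200,
400, 700 s/mm²) three points enter the restricted fit. Log-linear OLS was
chosen over nonlinear least squares because it is the standard, direct
estimator for a three-point decay; the test suite keeps an independent
nonlinear (Levenberg–Marquardt) oracle and shows the two routes agree to a
few percent per voxel at SNR 50. Voxels with any non-positive signal among
the used b-values are flagged invalid rather than imputed — the log
transform is undefined there, and excluding them keeps ROI means honest.
Negative fitted ADC (possible in pure noise) is retained by default and can
be clamped at zero with `clamp_negative = TRUE`.

## The three-class mixture and the tumor threshold

`fit_gmm()` runs standard expectation-maximization for a univariate
Gaussian mixture on all SUV values inside the user-supplied lesion crop.
Three classes encode the physics of a blurred hot lesion: *background*
(lowest mean), *unknown* (intermediate — chiefly partial-volume voxels at
the lesion rim), and *tumor* (highest mean). Components are relabeled by
ascending mean after fitting; ties break by ascending variance.

Numerical choices:

- **Initialization**: k-means++ seeding (`kmeanspp_init()`), the
  conventional default for mixture fitting; 5 restarts with seed-derived
  sub-seeds, best final log-likelihood wins.
- **Convergence**: relative log-likelihood change below 1e-6, capped at
  500 iterations; hitting the cap sets `converged = FALSE` rather than
  erroring. The log-likelihood trace is stored and asserted non-decreasing
  in the tests.
- **Variance floor**: 1e-6 times the data variance, the standard safeguard
  against component collapse onto repeated values; a floored component
  with weight below 1e-6 raises a `degenerate` diagnostic.
- **Identifiability precondition**: at least `2k` distinct values.

The tumor mask is *not* the raw maximum-posterior assignment. Voxels of the
intermediate class are counted as non-tumor, and the decision boundary is
the intersection of the weighted densities of the unknown and tumor
components: equating the two log densities gives a quadratic in `x`
(`tumor_threshold()`), whose root strictly between the two means is the
threshold; the mask is the strict exceedance `{SUV > t*}`. This
down-weights partial-volume rim voxels that posterior assignment would
sometimes hand to the tumor class. Open points resolved here and
documented as package conventions: the intersection is solved on
*weighted* densities (the standard mixture decision boundary — the
unweighted crossing would ignore class prevalence); the mask uses strict
`>`; when no root lies between the means (possible with extreme
weight/variance ratios) the midpoint `(μ_u + μ_t)/2` is used and flagged
`midpoint_fallback`. `class_assign()` exposes the plain posterior argmax so
the two rules can be compared case by case.

The comparator segmenters pin their boundary conventions explicitly: the
fixed threshold is strict (`SUV > 2.5`, may legitimately return an empty,
flagged mask when uptake has fallen below the cut), while the percent-max
rule is inclusive (`SUV ≥ 0.42 · max`), so the maximum voxel always
survives and the mask is never empty; the latter is invariant to positive
rescaling of the SUV map, the former deliberately not.

## Agreement metrics

Area is voxel count times voxel area (reported in cm²); mean ADC is taken
over mask voxels with a valid fit only, while the voxel count is reported
for the full mask. Dice is `2|A∩B|/(|A|+|B|)` with two pinned degenerate
conventions: both masks empty compares two identical (empty) segmentations
and returns 1 with a flag; exactly one empty returns 0. The center of
gravity is the unweighted centroid of member-voxel centers — the metric
evaluates the segmentation geometry, so intensity weighting would mix the
two concerns. Centroid displacement is reported raw in mm and, because
"normalized by the reference area" is dimensionally ambiguous, also as the
dimensionless `cog_mm / (10 · sqrt(area_cm2))` (displacement over the
square root of the reference area expressed in mm); the sqrt-area form is
canonical here precisely because it is scale-free, and the raw value is
always alongside.

## Cohort statistics

`cohort_report()` emits, per segmentation method: paired t and Pearson
correlation of area and mean ADC against the reference rows, and Welch
(unequal-variance — the safer default when nothing is known about group
variances) two-sample t tests between untreated and treated groups for
area, ADC, Dice and centroid displacement. All two-sided. Every raw p value
emitted by one invocation forms the Benjamini–Hochberg family; adjusted
p values are reported next to raw ones. Repeated scans of one patient are
treated as independent data sets — a fidelity-over-purity choice matching
how such cohorts are commonly tabulated, and a documented caveat. Paired
tests with constant differences (zero variance) are flagged degenerate
rather than reporting an infinite statistic.

## The lesion phantom: what it emulates, and what it does not

`make_phantom()` builds a 96 × 96 slice at 2 × 2 mm (the in-plane DWI
resolution of the emulated protocol) containing:

- a tumor as an ellipse (default semi-axes 16 × 12 mm, area ≈ 6 cm²,
  the scale of a locally advanced breast lesion's central slice) with a
  smooth random harmonic boundary perturbation (`lobularity`, default
  0.15) for realistic non-elliptical outlines;
- heterogeneous uptake: background SUV 1.0 (sd 0.1, i.i.d. Gaussian) and
  tumor SUV 8.0 with a spatially correlated Gaussian field (sd 2.0,
  correlation length 8 mm) — a high-contrast FDG-avid lesion with
  25% intratumoral variation;
- partial volume: a linear blend over a 4 mm rim, followed by a 4 mm
  full-width-half-maximum Gaussian blur of the whole SUV map standing in
  for the PET reconstruction filter of the emulated scanner protocol;
- diffusion: ADC 0.96 × 10⁻³ mm²/s inside the tumor (cellular carcinoma)
  against 2.0 × 10⁻³ outside (normal tissue), sharp at the true boundary;
  DWI signals `S_0 · exp(−b · ADC)` at the six protocol b-values with
  Rician magnitude noise (sigma 20 at S0 = 1000, i.e. SNR 50);
- a reference mask standing in for a manual DCE delineation: the same
  lesion boundary with a smooth angular jitter (sd in mm) and a rigid
  offset — a geometric proxy, not a simulated contrast-kinetics image;
- treatment: a single fraction `f` scales the uptake contrast by `1 − f`
  and moves tumor ADC to `ADC_t + f (ADC_bg − ADC_t)`, emulating declining
  glucose metabolism and rising diffusivity under neoadjuvant therapy.

`simulate_cohort()` draws per-case lognormal variation around these
defaults. The per-axis size jitter defaults to 0.35, chosen so the
cohort's lesion-area spread matches the roughly twenty-fold tumor-volume
range reported for locally advanced breast cancer cohorts; treated cases
draw `f` uniformly from 0.3–0.9, spanning partial to near-complete
metabolic response (at the upper end the lesion's maximum SUV falls below
2.5, reproducing the regime in which the fixed threshold finds no tumor at
all).

What passing tests on these phantoms demonstrates: the estimators are
exact on noiseless inputs, the EM and threshold machinery behave as
specified, and the qualitative method ordering (the adaptive mixture
tracks the true extent where the fixed cut fails on treated lesions and
the percent-max cut over-segments them) emerges from the physics built
into the phantom. What it does not demonstrate: performance on real
PET/MRI, where uptake distributions are not Gaussian-mixture-shaped,
the DCE reference disagrees with PET for physiological (not geometric)
reasons, registration is imperfect, and lesions can be multi-focal. Two
known simplifications deserve emphasis: the single treatment fraction
couples the metabolic and diffusion responses, whereas in patients the ADC
response is typically weaker than the metabolic one, so treated-cohort
mean ADC values here run higher than clinical tables; and the smooth
correlated uptake field under-represents focal hot spots, whose
high maxima are precisely what breaks percent-of-maximum thresholds in
practice — in exploratory runs, strongly multimodal or hot-spot fields
also defeat the three-class mixture itself (the maximum-likelihood fit
dedicates the tumor class to the hot tail), so cohort-level superiority of
the mixture over the percent-max rule on untreated phantoms is a
fixed-fixture demonstration here, not a seed-universal property.

## Problem sizes and determinism

Everything stochastic takes an explicit integer seed: phantoms embed one
in their spec, `fit_gmm()` derives restart sub-seeds from its `seed`
argument, and cohort runs derive per-case sub-seeds reproducibly from the
master seed, so reruns are bit-identical. The shipped validation uses
problem sizes chosen to exercise the estimators well inside a
laptop-minute budget: 100-draw exactness sweeps for the ADC fit, 20
simulations of n = 3000 for mixture recovery, 100 random fits against a
10⁻⁵-step density-crossing grid scan, the full 53-phantom default cohort
run twice for determinism, and 1000 simulated 30-case cohorts for the
paired-t null calibration.

## Known limitations

Single-slice 2-D only (3-D inputs require an explicit slice index);
inputs must already share one grid — no registration or resampling is
performed; no DICOM ingestion; no connected-component post-processing of
masks; the number of mixture classes is fixed at three, and crop selection
remains the user's responsibility, to which the method is sensitive.
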