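# petgmm

Semi-automated breast-lesion segmentation on simultaneous PET/MRI, with
diffusion biomarker extraction and a full synthetic-validation pipeline.

## The problem

Monitoring neoadjuvant treatment response in breast cancer relies on tumor
delineation. The clinical standard — manual segmentation on dynamic
contrast-enhanced (DCE) MRI — is slow, observer-dependent, and requires
gadolinium. On simultaneous PET/MRI the 18F-FDG uptake map is intrinsically
co-registered with diffusion-weighted MRI (DWI), so a data-driven
segmentation of the PET standardized uptake value (SUV) map can replace the
manual DCE region of interest (ROI) as the mask from which diffusion
biomarkers — tumor area and mean apparent diffusion coefficient (ADC) — are
read out.

`petgmm` implements that workflow on 2-D single-slice data:

- **SUV maps** from activity concentration: `SUV = C [kBq/mL] · weight [kg]
  / dose [MBq]`.
- **Perfusion-insensitive ADC maps** by per-voxel ordinary least squares of
  `log S_b` against `b` under the mono-exponential model
  `S_b = S_0 · exp(−b · ADC)`, restricted to b ≥ 200 s/mm² so the fast
  pseudo-diffusion (perfusion) component at low b does not inflate ADC.
- **GMM–PET segmentation**: a user-supplied rectangular crop around the
  lesion; a 3-component univariate Gaussian mixture fitted to the cropped
  SUV values by expectation-maximization with k-means++ initialization and
  restarts. The components, ordered by mean, are *background*, *unknown*
  (partial-volume / intermediate uptake), and *tumor*. The tumor mask is
  `{SUV > t*}` where `t*` solves the weighted-density intersection
  `w_u N(t*; μ_u, σ_u²) = w_t N(t*; μ_t, σ_t²)` between the unknown and
  tumor components (a quadratic in `t*`; the root between the two means is
  taken). Treating "unknown" voxels as non-tumor counteracts overestimation
  from partial-volume blur.
- **Comparator thresholds**: fixed `SUV > 2.5`, and `SUV ≥ 0.42 · SUV_max`.
- **Agreement metrics**: ROI area (cm²) and mean ADC over valid fit
  voxels; Dice coefficient `2|A∩B|/(|A|+|B|)`; center-of-gravity
  displacement in mm, optionally normalized by the square root of a
  reference ROI area.
- **Cohort statistics**: paired t and Pearson correlation against the
  reference per method, Welch t between untreated and treated groups,
  Benjamini–Hochberg correction across the emitted family.
- **Digital lesion phantoms**: perturbed-ellipse tumors with spatially
  correlated heterogeneous uptake, a partial-volume rim plus 4 mm
  reconstruction blur, multi-b DWI with Rician noise, a jittered reference
  mask standing in for a manual DCE delineation, and a treatment-effect
  fraction that moves uptake and diffusivity toward background.

## Worked example

```r
library(petgmm)

ph <- make_phantom(phantom_spec(seed = 2, dce_jitter_mm = 1, dce_offset_mm = 0.5))
cropped <- crop_slice(ph$suv, ph$crop)
seg <- segment_gmm(cropped, seed = 102)
print(seg$fit)
#> <mixture_fit> 3 components on 528 values, logLik -711.681 (converged after 43 iter)
#>   background w = 0.388, mean = 1.011, sd = 0.045
#>   unknown    w = 0.306, mean = 3.053, sd = 1.706
#>   tumor      w = 0.306, mean = 8.298, sd = 0.891

rows <- run_case(ph$suv, ph$dwi, ph$crop, ph$reference,
                 case_id = "lesion01", group = "untreated", seed = 102)
print(rows[, c("method", "threshold", "area_cm2", "mean_adc", "dice", "cog_mm")],
      digits = 3)
#>            method threshold area_cm2 mean_adc  dice cog_mm
#> 1       reference        NA     5.96  0.00103 1.000  0.000
#> 2         gmm_pet      6.31     6.52  0.00104 0.923  0.895
#> 3       suv_fixed      2.50     9.76  0.00134 0.758  0.737
#> 4 suv_percent_max      4.15     8.12  0.00121 0.847  0.652
```

The mixture places background at SUV ≈ 1, a broad intermediate class over
the partial-volume rim, and the tumor at SUV ≈ 8.3; the intersection
threshold 6.31 yields a mask agreeing with the jittered reference at Dice
0.92 with sub-millimeter centroid displacement, while the fixed-2.5 and
42%-of-max cuts over-segment this heterogeneous lesion (Dice 0.76 / 0.85).
The mean ADC read out under the GMM mask (1.04 × 10⁻³ mm²/s) matches the
reference ROI's value.

A cohort run produces a per-case long table, a group summary, and a
BH-adjusted statistical report:

```r
run <- run_cohort(n_untreated = 24, n_treated = 29, seed = 1)
write_cohort(run, "cohort_out")
```

## Command line

A thin wrapper over the same functions lives at `inst/cli/petgmm`
(subcommands `phantom`, `segment`, `metrics`, `stats`, `cohort`):

```sh
Rscript inst/cli/petgmm phantom --out ph/
Rscript inst/cli/petgmm segment --suv ph/suv.nii.gz --crop ph/crop.csv \
    --method gmm --seed 3 --out mask.nii.gz --json fit.json
Rscript inst/cli/petgmm cohort --n-untreated 24 --n-treated 29 --seed 1 --out co/
```

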