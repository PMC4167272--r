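# dwcmr

Contrast-free characterization of chronic myocardial infarction from
diffusion-weighted cardiovascular MR (dwCMR), as a tested R package.

Late gadolinium enhancement (LGE) is the clinical gold standard for sizing
and locating chronic infarct, but gadolinium is contraindicated in a large
fraction of infarct patients with renal disease. Chronic infarcts are
fibrotic, and fibrosis elevates the apparent diffusion coefficient (ADC) of
myocardial water, so a motion-compensated diffusion-weighted acquisition
can delineate scar without contrast. This package implements the complete
analysis chain needed to validate that claim against LGE, for researchers
working with short-axis cardiac DWI:

- **ADC mapping** — two-point monoexponential fit per direction,
  `ADC = ln(S0/S_b)/b`, and the trace map
  `ADC = (ADC_x + ADC_y + ADC_z)/3` (`fit_adc()`, `trace_adc()`);
- **semi-automatic infarct quantification** — the 6-SD threshold criterion
  (voxels above `mean + 6 SD` of a remote ROI) and the FWHM region-growing
  criterion (seed region at >= 50% of the seed, final mask at >= 50% of the
  seed region's maximum), run identically on ADC maps and LGE images, with
  infarct volume as a percentage of the imaged LV and binary transmurality
  (`threshold_classify()`, `fwhm_classify()`, `infarct_volume_pct()`,
  `transmurality()`);
- **two-step co-registration** — automatic cine phase matching, then
  non-rigid B-spline point-based registration between cine phases, with the
  transform applied to the LGE image so registration error stays
  independent of the delineation comparison (`select_matching_phase()`,
  `fit_bspline()`, `apply_transform()`);
- **regional wall motion** — 100 evenly spaced chords per slice from cine
  contours, maximal endocardial excursion per chord, and the <= 3 mm
  akinesis rule (`compute_chords()`, `chord_displacement()`,
  `classify_akinetic()`);
- **AHA 16-segment scoring** — 6/6/4 sectors over base/mid/apex with the
  any-voxel positivity rule (`assign_segments()`, `score_segments()`);
- **agreement statistics** — pooled 2x2 contingency tables, Cohen's kappa,
  sensitivity/specificity/PPV/NPV against an LGE gold standard, ICC(2,1),
  Pearson R^2, Bland-Altman, exact Wilcoxon signed-rank, Bonferroni control
  (`cohens_kappa()`, `icc()`, `bland_altman()`, `wilcoxon_signed_rank()`,
  `agreement_report()`);
- **a ground-truthed digital LV phantom** — three 6 mm short-axis slices at
  the protocol resolutions (2.1 mm DWI, 1.3 mm LGE, 1.4 mm cine, 35 cine
  phases), a transmural anteroseptal wedge infarct at ~11% of the imaged
  LV, ADC 1.4 (remote) vs 2.4 um^2/ms (infarct), radial excursion 8.3 vs
  0.9 mm, Rician noise, and an LGE image rendered in a deformed cardiac
  phase with a known ground-truth warp (`phantom_config()`,
  `generate_phantom()`, `simulate_cine()`);
- **gradient-preparation verification** — closed-form gradient moments and
  b-value of trapezoidal waveforms with refocusing markers, and a designer
  for the four-lobe quadra-bipolar preparation that nulls M0, M1 and M2
  while hitting a b-value target under amplitude and duration constraints
  (`moments()`, `b_value()`, `design_quadra_bipolar()`).

`run_study()` composes all stages into a seeded 11-subject study replica —
phantom cohort, ADC fitting, phase matching, registration, both
classifiers on both modalities, reviewer-placement replicas, AHA scoring,
wall motion, and the full statistical battery — and emits the regional,
volume-agreement, and location-agreement tables as data frames, CSV and
JSON.

## Worked example

```r
library(dwcmr)

st  <- generate_phantom(phantom_config(store_cine_images = FALSE))
adc <- with(lapply(st$dwi, fit_adc, b0 = st$b0, b = 400),
            trace_adc(x, y, z))

roi <- remote_roi_mask(st$truth$myocardium, st$truth$reference_angle,
                       st$truth$center)
unlist(mean_region_adc(adc, roi))
#>       mean         sd          n
#>  1.3977834  0.1150524 49.0000000

elev <- adc; elev$data <- adc$data - mean(adc$data[roi], na.rm = TRUE)
fw <- fwhm_classify(elev, infarct_seeds(st$truth$infarct),
                    st$truth$myocardium)
fw
#> <infarct_mask> method fwhm: 88 voxels (10.6% of myocardium)
infarct_volume_pct(fw, st$truth$myocardium)
#> [1] 10.62802
unlist(mean_region_adc(adc, fw$mask))
#>       mean         sd          n
#>  2.4120173  0.1272029 88.0000000
```

At the default SNR the remote myocardium reads 1.40 um^2/ms and the
FWHM-delineated infarct 2.41 um^2/ms — a ~70% elevation — and the FWHM
volume estimate (10.6% of the imaged LV) recovers the phantom's configured
infarct fraction. The diffusion preparation behind such an acquisition can
be checked directly:

```r
wf <- design_quadra_bipolar(400, 43, 105)  # b s/mm^2, mT/m, ms
wf
#> <gradient_waveform> 4 lobes, 1 refocusing marker(s), 86 ms
#>  amplitude ramp_up     flat ramp_down delay
#>  -18.60959       1 17.01228         1     0
#>   43.00000       1 17.01228         1     0
#>   43.00000       1 17.01228         1    10
#>  -18.60959       1 17.01228         1     0
attr(wf, "b")        # 400 within 0.5%
attr(wf, "moments")  # M0, M1, M2 residuals, all ~1e-9 or below
```

See `vignettes/dwcmr-methods.Rmd` for the model assumptions, parameter
choices, and limitations.

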