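---
title: "Methods: contrast-free infarct characterization with dwCMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contrast-free infarct characterization with dwCMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwcmr)
```

## The problem

Late gadolinium enhancement (LGE) is the clinical gold standard for sizing
and locating chronic myocardial infarction, but it requires a contrast agent
that is contraindicated in patients with severe renal disease. Chronic
infarcts are fibrotic, and fibrosis raises the apparent diffusion
coefficient (ADC) of myocardial water; diffusion-weighted cardiovascular MR
(dwCMR) can therefore, in principle, delineate chronic infarct without
contrast — provided bulk cardiac motion does not masquerade as diffusion.
This package re-implements, as tested and reusable code, the complete
analysis chain of such a validation study: ADC mapping, semi-automatic
infarct quantification on both ADC and LGE, cine-mediated co-registration,
chord-based regional wall motion (RWM), AHA 16-segment scoring, and the
method-agreement statistics. A ground-truthed digital left-ventricle
phantom stands in for animal data, so every stage is verifiable against a
known answer.

## The forward model and ADC mapping

Diffusion weighting attenuates the spin-echo signal monoexponentially,
`S_b = S0 * exp(-b * ADC)`. With one non-diffusion-weighted image (b0) and
one image at `b = 400 s/mm^2` per encoding direction, the two-point fit is
the exact inversion `ADC = ln(S0 / S_b) / b` (`fit_adc()`), reported in
um^2/ms (1 um^2/ms = 1e-3 mm^2/s; the unit conversion is applied exactly
once, at fit time). The trace ADC is the arithmetic mean over the three
orthogonal directions (`trace_adc()`), which removes first-order sensitivity
to fibre orientation.

Voxels with non-positive signal, or with `S_b > S0` (a negative fit), are
flagged invalid and excluded from regional means. We deliberately do not
clamp them to zero: clamping would bias regional means downward in exactly
the low-SNR regions where the question matters. This policy is a documented
choice; how the original analysis handled non-physical fits is not stated
anywhere we could verify.

## The digital phantom

`phantom_config()` / `generate_phantom()` build a three-slice short-axis LV
(base/mid/apex, 6 mm slices) with:

* grids and spacings per contrast — 2.1 mm (DWI/b0), 1.3 mm (LGE), 1.4 mm
  (cine), matching the acquisition protocol the analysis targets;
* end-diastolic endo/epicardial radii of 21/29, 17/27 and 12/22 mm. With a
  60 degree anteroseptal wedge spanning the mid and apical slices this puts
  the transmural infarct at 11.0% of the three-slice LV myocardium, the
  volume regime of the emulated study;
* true trace ADC of 1.4 um^2/ms in remote myocardium, 2.4 in infarct,
  3.0 in the blood pool; b0 amplitude 100 (myocardium);
* an LGE-like image rendered in the geometry of a *different* cardiac phase
  (default phase 8 of 35, contraction factor ~0.43), with hyperintense
  infarct and a blood pool isointense with remote myocardium, as in a
  well-nulled PSIR acquisition. The phase offset gives the registration
  stage real work with a known ground-truth deformation;
* a 35-phase cine series with analytic endo/epicardial contours. Phase 0 is
  end-diastole; radial endocardial excursion peaks at 8.3 mm in remote
  myocardium and 0.9 mm in the infarct zone, with a motion-deficit plateau
  extending 50 degrees beyond the wedge (10 degree ramp) and a 2.5 mm
  "tethering" excursion on the adjacent basal slice. The widened deficit
  reflects the physiological observation that akinesis extends beyond scar,
  and guarantees that akinetic segments encapsulate infarct-positive
  segments under the any-voxel scoring rule;
* Rician noise: the magnitude of complex Gaussian noise,
  `|S + n1 + i n2|`, with `sigma = reference / SNR`. No SNR is documented
  for the target acquisition, so the default (SNR 30 on the remote b0
  amplitude; 40 for LGE) was fixed once as a typical 3 T figure, and the
  test suite sweeps SNR rather than asserting any single value.

Masks use centre-of-voxel inclusion (the simplest rule that is exactly
testable); the myocardium is the epicardial disk minus the endocardial disk
per slice, and the ground-truth infarct is always a subset of it. Voxels
are rendered as pure tissue classes — there is no partial-volume mixing at
generation time (interpolation during warping introduces it downstream,
which is the realistic place for it).

Per-subject cohort variation (`study_config()`) draws the wedge's angular
extent uniformly on 25–95 degrees, spanning infarct fractions of roughly
5–17% (mean 11%). The wedge centre stays fixed at the anteroseptal
(LAD) territory: the emulated study design induced infarcts in one
territory only.

What the phantom does *not* emulate: k-space/TSE readout artifacts,
navigator/ECG gating, B1 inhomogeneity, realistic torso anatomy, papillary
muscles, through-plane motion, and biological ADC heterogeneity (remote ADC
is spatially uniform, so its SD under noise is purely thermal). Passing
tests therefore demonstrate correctness of the *analysis*, not performance
on real animals.

## Diffusion-preparation verification

`gradient_waveform()` represents a preparation axis as trapezoidal lobes
plus refocusing-pulse markers that invert effective polarity. Moments
`M_n = integral G_eff(t) t^n dt` and the b-value
`b = gamma^2 integral q(t)^2 dt`, `q = integral G_eff`, are integrated in
closed form per segment (the integrands are polynomials of degree at most
4), so the only numerical error is float rounding; a composite-Simpson
oracle in the tests is exact for the same reason and independent of this
code path.

`design_quadra_bipolar()` builds the four-lobe M1M2-nulled preparation: for
a fixed symmetric timing (four equal trapezoid lobes, fixed ramps, one
refocusing gap) the three moment constraints are *linear* in the four lobe
amplitudes, so the amplitude pattern is the 1-D null space of the moment
map, scaled to the hardware maximum; a one-dimensional search over the
flat-top duration then matches the b-value target. Moments are nulled by
construction (to float precision), and infeasibility is reported together
with the maximal achievable b at the given constraints. Whether the quoted
preparation window includes the refocusing-pulse durations is not
documented; the designer treats it as the total available window, with the
refocusing gap (default 10 ms) counted inside it.

## Co-registration

Registration never touches the images being compared: the cine phase
matching each acquisition is found automatically as the phase minimizing
the mean symmetric contour-to-contour distance (`select_matching_phase()`;
intensity-independent, so it works across contrasts; ties break to the
earlier phase), the two cine phases are registered, and the resulting
transform is applied to the LGE image. Landmarks are contour points
resampled at equal arc length (default 50 per contour, endo and epi, per
slice); the transform is a per-slice cubic B-spline free-form deformation
fitted by penalized least squares with a discrete bending-energy penalty
(control spacing 25 mm, weight 1e-3 by default). With zero regularization
the fit falls back to the minimum-norm exact least-squares solution, so
identity and pure-translation cases are recovered to machine precision.
Resampling is a backward warp with bilinear (default) or nearest
interpolation. Landmark choice, lattice spacing and penalty weight are
config defaults to be sensitivity-tested — the original implementation's
values are not documented anywhere.

Equal-arc-length correspondence is approximate when the contour shape
changes between phases; the residual is a tangential slide along a
near-isointense boundary and has little effect on the resampled image. The
registration tests therefore check two things separately: the fit against
landmark pairs sampled from the phantom's exact displacement field
(sub-half-pixel recovery), and the end-to-end effect on LGE-derived
quantities in the pipeline tests.

## Infarct quantification

Two standard semi-automatic classifiers, run identically on the ADC map and
the co-registered LGE image:

* **n-SD threshold** (`threshold_classify()`): infarct = myocardial voxels
  above `mean + 6 SD` of a remote ROI. The ROI is standardized as a
  60 degree sector of the most basal slice's lateral wall — the territory
  farthest from an anteroseptal infarct. With a degenerate SD of zero the
  cutoff collapses to the remote mean (strictly-greater comparison). The
  6 SD multiplier follows one established convention; 2–6 SD variants exist
  in the literature, and the multiplier is a parameter.
* **FWHM region growing** (`fwhm_classify()`): a seed region is grown
  (4-connected, in-plane) from a manually placed seed over voxels at or
  above 50% of the seed's value; the final mask is all myocardial voxels at
  or above 50% of the seed region's maximum, restricted to connected
  components that intersect the seed region. The restriction resolves an
  ambiguity in the usual verbal statement of the rule (global vs
  region-restricted thresholding); we chose region-restricted because a
  global half-maximum cut would classify disconnected remote noise islands
  as infarct.

One subtlety matters when the FWHM criterion is applied to ADC maps. The
rule was designed for hyperenhancement images whose remote tissue sits near
zero; on an ADC map the remote baseline (1.4 um^2/ms) exceeds half the
infarct level (2.4/2 = 1.2), so the literal rule floods the whole
myocardium. The pipeline therefore classifies on the *signal elevation
above remote* — the map minus its remote-ROI mean. This is exactly the
half-maximum-above-baseline reading of "full width at half maximum", is a
no-op for the threshold mask (a constant shift moves the cutoff equally),
and reduces to the literal rule on nulled-background LGE. `fwhm_classify()`
itself implements the literal quoted rule, so both forms are available.

Infarct volume is reported as a percentage of the three-slice LV
myocardial volume (`infarct_volume_pct()`); the constant voxel volume
cancels. Transmurality (`transmurality()`) asks whether each connected
infarct spans endocardium to epicardium along every radial ray within its
angular span, with a one-voxel tolerance at each surface — a strict rule:
a single interior gap defeats it, which is the intended behaviour for a
binary "completely transmural" call.

Connectivity is 4-connected and in-plane only: with 6 mm slices and three
slice positions, through-plane growth would leap across more than a
centimetre of unimaged myocardium. Multi-slice lesions take one seed per
lesion-bearing slice.

## Wall motion and AHA scoring

100 evenly spaced chords per slice are cast as rays from a fixed LV centre
(the reference-phase epicardial centroid — a floating per-phase centre
would cancel part of the motion), intersected with the contours
(`compute_chords()`); each chord's RWM is the maximal excursion of its
endocardial intersection across phases relative to the reference phase
(`chord_displacement()`). A segment is akinetic when the *mean* absolute
displacement of its chords is at or below 3 mm (`classify_akinetic()`);
mean-aggregation was chosen over any-chord for noise robustness, as the
verbal rule does not specify the aggregation. The radial-ray construction
is a documented stand-in for proprietary centreline chord algorithms.

AHA scoring (`assign_segments()`, `score_segments()`) divides basal and mid
slices into six 60 degree sectors and the apical slice into four 90 degree
sectors, numbered counter-clockwise from the anterior reference ray
(16 segments; the 17th apex cap is not acquired in a three-slice protocol).
A segment is infarct-positive if it contains *any* classified voxel — the
any-voxel rule, exactly as conventionally stated.

## Agreement statistics

`contingency()` pools all segments across subjects (11 x 16 = 176) into one
2x2 table; significance is tested on the pooled scores, not per segment.
Cohen's kappa uses the standard chance-corrected form and is symmetric
under table transposition. Diagnostic metrics treat LGE as the gold
standard and report undefined (not zero) on empty marginals. Bland-Altman
reports bias and 1.96-SD limits of agreement of `ADC - LGE` (the sign
convention is stated in all outputs). The ICC is fixed to the two-way
random-effects, absolute-agreement, single-measure form ICC(2,1), computed
from the two-way ANOVA mean squares — the citation trail behind such
analyses identifies the Shrout–Fleiss framework but not the form, and
absolute agreement is the conservative choice for method comparison. The
Wilcoxon signed-rank test drops zero differences, uses the exact
distribution for 25 or fewer untied pairs and a tie-corrected normal
approximation otherwise; the spatial-location family applies a Bonferroni
divisor of m = 11 (alpha 0.05/11 ≈ 0.0045), m being a config value.

The reviewer replica (`simulate_reviewers()`) perturbs only what human
reviewers chose — the remote-ROI centre (uniform ±10 degrees) and the FWHM
seed voxel (uniform ±2 voxels, resampled if it leaves the myocardium). It
probes pipeline sensitivity to placement; it is not a model of human
behaviour. A corollary of the two-stage FWHM rule is that seed jitter
within a unimodal lesion core leaves the mask unchanged, which the tests
assert.

## Numerical choices and problem sizes

* All randomness flows from one master seed; sub-seeds are derived
  arithmetically and kept below 2^31.
* Ray-polygon intersection tolerates rays through polygon vertices
  (half-open edge parameter with a 1e-9 lower tolerance) and rejects
  non-star-shaped contours.
* The default cohort is 11 subjects at full image size, which runs the
  entire replica in well under a minute; unit tests use a reduced phantom
  (120 mm field of view, 12 cine phases) chosen to preserve the geometry
  and contrast levels while keeping the suite fast.
* In the noise-free limit the ADC round trip is exact to float precision
  and both classifiers reproduce the ground-truth mask exactly; segment
  agreement between ADC and LGE is then perfect (kappa = 1), while volume
  ICC remains marginally below 1 because the two modalities discretize the
  same anatomy on different grids (2.1 vs 1.3 mm) — a floor set by
  geometry, not by the method.

## Known limitations

* The phantom's motion model is radial and in-plane; circumferential
  shortening, torsion and through-plane motion are absent, so chord RWM on
  real data will include components this phantom never exercises.
* The LGE blood pool is modelled isointense with remote myocardium;
  bright-blood LGE would interact with the endocardial boundary under
  interpolation and is not covered.
* Threshold-method LGE volumes inherit a small positive bias from
  interpolation at the infarct boundary after warping (visible in the
  Bland-Altman bias of the replica); FWHM is less affected, mirroring its
  reported robustness advantage.
* Agreement statistics pool segments across subjects, ignoring
  within-subject correlation — faithful to the emulated analysis, but a
  mixed-model treatment would be more defensible statistically.
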