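---
title: "The local-projection partial-volume correction: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The local-projection partial-volume correction: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the science inside `lppvc`: the forward model, the
local-projection (LP) estimator, the synthetic phantoms used to validate
it, and the numerical and design decisions that were genuinely open —
together with what the test suite does and does not establish.

## 1. The problem

PET resolution (4–8 mm full width at half maximum, FWHM) is comparable to
the size of the structures of interest in atherosclerotic plaque imaging
(plaque volumes from tens to hundreds of mm³). The reconstructed activity
of such a lesion is diluted into its surroundings — the partial volume
effect — and the clinical figure of merit, the lesion-to-background ratio
(LBR), is biased low by factors that grow rapidly as lesions shrink.
Post-hoc image-space corrections must undo a blur the reconstruction has
already baked in; the LP method instead goes back to projection space,
where the data still carry the un-reconstructed information.

## 2. Forward model

The acquisition model is a deliberately transparent, desk-scale
idealization:

* **Geometry.** Stack-of-slices 2D parallel-beam projection; by default 120
  views uniform over 180° and radial bins equal to the voxel pitch
  (2.03 mm isotropic voxels, the clinical reconstruction grid). The
  projector distributes each voxel into the two nearest radial bins with
  linear weights; the back-projector is its exact algebraic transpose
  (verified to `1e-6` relative, in practice machine precision), which the
  EM reconstruction and the LP fit both rely on.
* **Resolution.** A shift-invariant isotropic Gaussian PSF applied in image
  space before projection. This matches the assumption under which the
  method is derived; spatially-variant resolution is out of scope and is
  the main caveat for lesions far off-centre.
* **Attenuation.** Per-bin factors `exp(-∫ mu dl)` computed from the
  attenuation map by the same ray transform (two-compartment default:
  water 0.0096 mm⁻¹, bone/calcification 0.017 mm⁻¹ at 511 keV).
* **Scatter.** An additive sinogram term with the two properties the
  correction chain actually uses — smoothness and a controlled magnitude.
  It is built by convolving the unscattered trues with a wide (80 mm FWHM)
  Gaussian in sinogram space and rescaling so that
  `total(scatter) = SF/(1-SF) × total(trues)` for scatter fraction `SF`
  (default 0.2). A full single-scatter physical simulation would change
  nothing about the method's contract, which only requires a known
  additive term.
* **Counting.** Independent Poisson counts per bin. `count_scale`
  (counts per kBq/mL·mm³ over the whole acquisition) folds in duration and
  sensitivity; simulations are calibrated to a target expected count total.

## 3. Reconstruction

`osem()` implements ordered-subsets EM with the update
`x <- x / sens_S * P_S^T( y_S / (P_S x + s_S) )`, subsets assigned
round-robin over angles, attenuation and normalization inside `P`
(multiplicative) and scatter as the additive `s`. Defaults follow the
clinical protocol of the validation studies: 5 iterations, 21 subsets,
optionally a 5-mm Gaussian postfilter; resolution modelling
(`psf_in_recon = TRUE`) puts the Gaussian PSF inside `P` and reproduces the
characteristic sharpening-plus-edge-overshoot of PSF reconstructions.
Numerical guards: a `1e-10` floor in denominators, and voxels with total
sensitivity below `1e-8` of the maximum (outside the measured field of
view) frozen at zero. The initial image is a uniform positive constant
matched to the measured count total; with noise-free matched data the
iteration converges to the truth (checked at 5% in the phantom interior)
and the per-iteration Poisson log-likelihood is non-decreasing.

## 4. The LP estimator

Within a VOI partitioned into `J` tissues, the model for measured bin `i`
is `lambda_i = sum_j A_j P_ij + g_out_i`:

* `P_ij` — forward projection (PSF, attenuation, normalization, no
  scatter) of tissue `j`'s indicator at unit activity. The fit is
  restricted to the support bins whose rays intersect the VOI, keeping the
  problem local.
* `g_out_i` — counts from outside the VOI: the reconstructed image with
  VOI voxels zeroed, forward-projected with full physics, plus the scatter
  estimate.
* `A_j` — solved by weighted least squares. Weights follow the Poisson
  variance of the *model* counts via one reweighting pass: an ordinary LS
  fit provides fitted expectations `lambda_hat`, then
  `w_i = 1/max(lambda_hat_i, 1)`. Weighting by the measured counts
  instead is badly biased in the few-counts-per-bin regime (a bin that
  fluctuates low would be over-trusted; at the count levels used here this
  halves the recovered lesion activity). The reweighted LS solution agrees
  with the exact Poisson maximum-likelihood (EM) solution to better than
  0.1% in all regimes we exercised, while staying a linear solve.
  Non-negativity (`A_j >= 0`) is enforced by an NNLS fallback. Nearly
  collinear tissue projections (pairwise correlation > 0.999 on the
  support) abort with an error rather than return an ill-conditioned fit.

Substituting the fitted `A_j` into the VOI voxels, re-projecting with full
physics and re-reconstructing yields the corrected image; voxels outside
the VOI are never modified by the substitution (asserted bit-exactly).

### Estimator details that mattered

Three choices materially affect accuracy at realistic count levels and are
therefore worth recording:

1. **The image used for `g_out`.** The uncorrected 5×21 OSEM image at
   around 10⁶ counts is noisy enough that forward-projecting it injects
   broad, seed-specific local errors into `g_out`, which the fit then
   attributes to the tissues. The default pipeline therefore estimates
   `g_out` from a deliberately under-iterated, smoothed companion
   reconstruction (2 iterations × 21 subsets, 6-mm Gaussian;
   `g_out_recon()`). For *FWHM calibration* the companion is additionally
   reconstructed **with** resolution modelling at each candidate width:
   an image reconstructed without PSF modelling is itself blurred, and
   masking it at the VOI then re-blurring under-counts the background
   spill across the VOI boundary — a second-order effect at 4 mm that
   becomes first-order at 8 mm.
2. **VOI margin.** The margin trades locality against the stability of the
   local-background estimate. The package default is 12 mm (≈1.5× the
   widest PSF considered); the phantom evaluation experiments use 20 mm
   because at ~10⁶ counts the 12-mm shell leaves the fitted background
   noise-limited. The VOI can be intersected with a body contour
   (`restrict`) so the background tissue is not diluted by out-of-body
   voxels — standard practice, and necessary for spheres close to the
   phantom edge.
3. **Which image the PET segmentation sees.** The background-adapted
   half-max isocontour is drawn on the reconstruction smoothed with a
   light 3-mm Gaussian in the thorax experiment: the unfiltered OSEM
   image's maximum is a single-voxel noise spike (degenerate one-voxel
   segmentations whose fitted activity overshoots the truth), while the
   5-mm protocol postfilter over-dilutes sub-voxel lesions and caps the
   achievable recovery. The *quantified* image remains the protocol's
   5-mm postfiltered image.

## 5. Synthetic phantoms and study conditions

All evaluations run on generated data; the generator is deterministic for
a fixed specification and also records the *intended* (pre-rasterization)
lesion activities, which serve as the ground-truth reference even when a
lesion is smaller than a voxel.

* **Image-quality phantom.** Torso-sized elliptical cylinder (semi-axes
  118 × 88 mm — the largest torso cross-section the 128 × 2.03 mm grid
  accommodates), six spheres of 10–37 mm on a 57.2-mm ring, background
  4.8 kBq/mL, sphere:background 4.95 (sphere activity 23.76 kBq/mL).
  Acquisition analogue: 4-mm PSF, 20% scatter, ~10⁶ expected counts.
* **Thorax phantom.** Three spherical lesions declared by volume (36, 31,
  18 mm³ → diameters 4.09, 3.90, 3.25 mm, i.e. at or below the 2.03-mm
  voxel pitch) at 70:1 over a 4.0 kBq/mL background. Sub-voxel lesions are
  rasterized as fractional occupancy times intended activity, which
  preserves activity mass exactly — the voxelized peak is legitimately
  diluted. Acquisition analogue: 4-mm PSF and 5×10⁶ expected counts.
  Both follow the emulated protocol rather than being free dials: the
  thorax scan corresponds to a 10-minute acquisition at the count rate
  that yields 10⁶ counts per standard 2-minute bed, and the 4-mm
  acquisition PSF matches the effective pre-filter resolution of the
  emulated scanner's standard reconstruction — with a substantially wider
  PSF the postfiltered image peak of a 36-mm³ lesion is diluted to the
  point where the uncorrected LBRs of such a protocol cannot arise at
  all.
* **Carotid section.** A vessel of blood-pool activity inside soft tissue
  with a single wall plaque of configurable volume and HU, plus an
  arterial reference segment 10–15 mm below the plaque for the
  background measurement, mirroring the patient analysis protocol. The
  volume sweep (`carotid_volume_sweep`) uses CT-threshold segmentation
  (the calcified-plaque pathway) and models the vessel lumen as its own
  tissue compartment.

What passing tests show — and what they do not: the phantoms share the
simulator's physics with the reconstruction and the LP fit (matched-model
validation). They establish the correctness and the noise behaviour of the
algorithmic chain, including its failure modes for sub-voxel lesions, but
not robustness to model mismatch a real scanner would add: spatially
variant PSF, misregistration between CT and PET (a rigid integer-voxel
`shift_volume()` utility is provided for synthetic misregistration
experiments, but no compensation is implemented), randoms, dead time and
motion.

## 6. Expected behaviour reproduced by the suite

The test suite asserts, among ~230 expectations:

* exact recovery of all `A_j` (to 1e-6) from noise-free matched data for
  J = 1, 2, 3 — the defining property of the estimator;
* recovery of the sphere ratio within 10% across the 17–37 mm spheres of
  the simulated image-quality phantom at ~10⁶ counts;
* several-hundred-percent ΔLBR for the sub-voxel thorax lesions, with the
  LP ratio nevertheless staying *below* the 70:1 truth (full recovery is
  impossible below the sampling limit of about three voxels per axis);
* the background-adapted 50% isocontour covering roughly 70–80% of the
  true sphere volume on 8-mm-resolution images;
* PSF FWHM calibration recovering 4 and 8 mm within ±0.5 mm from a 32-mm
  calibration sphere;
* a negative rank correlation between plaque volume and ΔLBR over the
  carotid sweep — the smaller the lesion, the larger the correction.

## 7. Numerical choices and degenerate inputs

* Sphere rasterization resolves boundary voxels on a 16³ sub-grid
  (volume error ≤ 0.25% down to 3.25-mm spheres); fully interior/exterior
  voxels are decided analytically.
* The FWHM calibration is a bounded scalar minimisation (tolerance
  0.1 mm); an argmin within 2 tolerances of a search bound is reported as
  "no minimum inside bounds" rather than returned.
* Division guards: `1e-10` in EM denominators; support bins for the LP fit
  require a tissue-projection sum above `1e-12` of its maximum.
* Degenerate inputs error early and descriptively: empty segmentations,
  VOIs touching the grid boundary, overlapping phantom lesions,
  rank-deficient tissue projections, scatter fractions ≥ 1, negative
  expectations.
* Every stochastic step takes an explicit integer seed; phantom
  construction is deterministic. The pipeline driver tags errors with the
  stage that raised them (`segment`, `voi`, `projections`, `fit`,
  `substitute`, `reproject`, `recon`).

## 8. Problem sizes

The default grids are deliberately desk-scale: 128 × 128 × 48 voxels at
2.03 mm for the evaluation phantoms (a full simulate–reconstruct–fit cycle
in well under a minute on one CPU), 48–64-wide grids for the unit-test
fixtures, which build in seconds. Clinical-scale matrix sizes (336–400
wide) are reachable through the specification fields but are not needed to
exercise any property of the method.
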