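# lppvc — local-projection partial-volume correction for PET

Quantitative PET of small hot lesions — atherosclerotic plaques imaged with
¹⁸F-NaF being the motivating case — is limited by the partial volume effect
(PVE): lesions of a few millimetres, comparable to the scanner's point-spread
function (PSF), appear diluted, and their lesion-to-background ratio (LBR)
can be underestimated several-fold. `lppvc` implements a projection-space
partial-volume correction, the **local projection (LP) method**, together
with everything needed to evaluate it end to end on synthetic data: digital
phantoms, an analytic acquisition simulator, OSEM reconstruction and the
quantification metrics used in plaque imaging.

## The method

Inside a small volume of interest (VOI) around the lesion, the image is
partitioned into `J` tissue compartments (the lesion, the local background,
optionally more). The expected counts in sinogram bin `i` are modelled as

```
lambda_i = sum_{j=1..J} A_j * P_ij + g_out_i
```

where `P_ij` is the resolution-blurred, attenuated, normalized projection of
tissue `j`'s indicator at unit activity, `A_j` is the unknown activity
concentration of tissue `j` (kBq/mL), and `g_out_i` collects the counts that
originate outside the VOI (estimated by forward-projecting the reconstructed
image with the VOI zeroed, plus the scatter estimate). The `A_j` are fitted
to the *measured projection data* by weighted least squares with
Poisson-variance weights, so the estimate does not inherit the resolution
loss of the reconstructed image. The fitted activities are substituted into
the image voxel-wise, the result is re-projected with full physics
(PSF, attenuation, scatter, optional Poisson noise) and re-reconstructed
with OSEM (5 iterations, 21 subsets), yielding the corrected (PVC) image.

Supporting machinery:

* **Phantoms** (`build_nema_iq`, `build_thorax_plaque`,
  `build_carotid_section`): voxelized activity / attenuation / HU / label
  maps; the image-quality phantom with six spheres (10–37 mm, ratio 4.95),
  a thorax with three sub-voxel "plaque-type" lesions (36/31/18 mm³ at
  70:1) and a synthetic carotid section. Lesions are rasterized with
  fractional occupancy, so sub-voxel lesions conserve activity mass.
* **Acquisition model** (`simulate_acquisition`, `forward_project`,
  `back_project`): slice-wise parallel-beam projector with an image-space
  Gaussian PSF, multiplicative attenuation, an additive smooth scatter term
  of controlled scatter fraction and Poisson counting noise; the
  projector/back-projector pair is an exact algebraic adjoint.
* **Reconstruction** (`osem`): ordered-subsets EM with scatter as an
  additive and attenuation/normalization as multiplicative terms, optional
  PSF-in-reconstruction (resolution modelling) and Gaussian postfiltering.
* **Quantification** (`lbr_max`, `lbr_a50`, `lbr_mean`, `delta_lbr`,
  `classify_plaque`, `fit_hyperbolic`, `association_stats`): the standard
  plaque figures of merit, HU classes (<110 non-calcified, 110–210 light,
  210–550 medium, ≥550 heavy) and trend/association statistics.
* **Segmentation** (`segment_ct_threshold`, `segment_pet_halfmax`):
  CT threshold (110 HU) for calcified lesions, background-adapted 50%
  isocontour for the rest.
* **Calibration** (`calibrate_fwhm`): recovers the effective Gaussian PSF
  width from an acquisition of a large sphere of known ratio.

## Worked example

Simulate the image-quality phantom (4-mm PSF, 20% scatter, ~10⁶ counts),
reconstruct, and run the LP fit per sphere with CT-based segmentation:

```r
library(lppvc)
res <- nema_lp_experiment(seed = 1)
print(res, row.names = FALSE, digits = 3)
#>  id diameter_mm lp_ratio gt_ratio rel_dev_pct
#>   3          17     4.57     4.95       -7.59
#>   4          22     4.79     4.95       -3.27
#>   5          28     5.24     4.95        5.77
#>   6          37     5.08     4.95        2.65
```

Each `lp_ratio` is the fitted lesion activity over the fitted local
background — the LP estimate of the sphere-to-background ratio. The true
ratio is 4.95; at this count level every sphere lands within ~8% of it,
where the uncorrected image underestimates the smaller spheres severely.

The thorax phantom with sub-voxel plaque-type lesions shows what the
correction buys for plaque-sized objects:

```r
th <- thorax_lp_experiment(seed = 1)
print(th, row.names = FALSE, digits = 3)
#>  id volume_mm3 lp_ratio image_lbr_max delta_lbr_pct gt_ratio
#>   1         36     32.0          6.32           407       70
#>   2         31     32.9          5.24           527       70
#>   3         18     13.0          3.48           273       70
```

`delta_lbr_pct` is the relative LBR increase of the LP estimate over the
uncorrected image measurement: several hundred percent for lesions this
small, while full recovery of the 70:1 truth is not possible for objects
below the sampling limit (about three voxels per axis).

A command-line pipeline over the same functions is installed at
`inst/cli/lppvc.R` (subcommands `phantom`, `simulate`, `recon`, `pvc`,
`quantify`, `calibrate`).

## Limitations

The simulator is a desk-scale idealization: 2D parallel-beam geometry per
slice, a shift-invariant Gaussian PSF and a convolution-based scatter
surrogate. The method's accuracy claims therefore concern the algorithmic
chain, not any specific scanner. See the methods vignette
(`vignettes/lp-pvc-methods.Rmd`) for the model, the estimator choices and
their rationale.
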