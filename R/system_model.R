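# Analytic acquisition model: image-space Gaussian PSF, slice-wise
# parallel-beam projection over 180 degrees, attenuation as per-bin
# multiplicative factors, scatter as an additive sinogram and Poisson
# counting noise. The forward/back projector pair is an exact algebraic
# adjoint, which the EM reconstruction and the local-projection fit rely on.

#' Projection-space data container
#'
#' Sinogram array indexed (angle, radial bin, slice) with its geometry.
#' Angles are uniformly spaced over 180 degrees.
#'
#' @param values 3D numeric array `(n_angles, n_radial, n_slices)`, >= 0.
#' @param angles view angles in radians (length `n_angles`).
#' @param radial_bin_mm radial bin width, mm.
#' @param counts_flag `TRUE` when the array holds integer measured counts
#'   rather than real-valued expectations.
#' @param seed optional seed recorded when counts were drawn.
#' @return An object of class `sinogram`.
#' @export
sinogram <- function(values, angles, radial_bin_mm, counts_flag = FALSE, seed = NULL) {
  if (length(dim(values)) != 3L) stop("sinogram: `values` must be a 3D array")
  if (dim(values)[1] != length(angles)) stop("sinogram: angle count mismatch")
  if (any(values < 0)) stop("sinogram: values must be non-negative")
  if (radial_bin_mm <= 0) stop("sinogram: radial bin must be > 0")
  if (counts_flag && any(values != round(values)))
    stop("sinogram: counts_flag requires integer values")
  structure(list(values = values, angles = as.numeric(angles),
                 radial_bin_mm = radial_bin_mm, counts_flag = counts_flag,
                 seed = seed), class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<sinogram> %d angles x %d radial (%.3g mm) x %d slices, %s, total %.4g\n",
              d[1], d[2], x$radial_bin_mm, d[3],
              if (x$counts_flag) "counts" else "expectations", sum(x$values)))
  invisible(x)
}

sino_like <- function(template, values, counts_flag = FALSE, seed = template$seed) {
  sinogram(values, template$angles, template$radial_bin_mm, counts_flag, seed)
}

stopifnot_same_geometry <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)) ||
      max(abs(a$angles - b$angles)) > 1e-12 ||
      abs(a$radial_bin_mm - b$radial_bin_mm) > 1e-12)
    stop("sinogram geometry mismatch")
  invisible(TRUE)
}

#' Projection geometry for an image grid
#'
#' Slice-wise parallel-beam geometry: one sinogram slice per image slice,
#' radial bins matching the voxel pitch, `n_angles` views uniform over
#' 180 degrees.
#'
#' @param img_dim image grid dimensions (integer triple).
#' @param voxel_size_mm isotropic voxel size, mm.
#' @param n_angles number of views (default 120).
#' @param n_radial number of radial bins (default: grid width).
#' @return List with `angles`, `n_radial`, `n_slices`, `radial_bin_mm`.
#' @export
projection_geometry <- function(img_dim, voxel_size_mm, n_angles = 120L,
                                n_radial = NULL) {
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (max(abs(voxel_size_mm - voxel_size_mm[1])) > 1e-9)
    stop("projection_geometry: isotropic voxels required")
  if (is.null(n_radial)) n_radial <- img_dim[1]
  list(angles = (seq_len(n_angles) - 1) * pi / n_angles,
       n_radial = as.integer(n_radial), n_slices = as.integer(img_dim[3]),
       radial_bin_mm = voxel_size_mm[1])
}

#' Acquisition physics bundle
#'
#' Groups everything the projector needs: PSF width, per-bin attenuation
#' factors, additive scatter expectation, per-bin normalization and the
#' global count scale. `count_scale` is the number of detected counts per
#' kBq/mL x mm^3 of activity over the full acquisition (before attenuation
#' losses); it folds in acquisition duration and sensitivity.
#'
#' @param psf_fwhm_mm full width at half maximum of the isotropic Gaussian
#'   point-spread function, mm (> 0).
#' @param attenuation `sinogram` of factors in (0, 1].
#' @param scatter `sinogram` of additive scatter expectations (>= 0), or
#'   `NULL` for none.
#' @param normalization `sinogram` of positive per-bin efficiencies, or
#'   `NULL` for uniform.
#' @param count_scale positive real, detected counts per kBq/mL x mm^3.
#' @param img_dim image grid dimensions the model projects from.
#' @param voxel_size_mm isotropic voxel size, mm.
#' @return An object of class `system_model`.
#' @export
system_model <- function(psf_fwhm_mm, attenuation, scatter = NULL,
                         normalization = NULL, count_scale = 1,
                         img_dim, voxel_size_mm) {
  if (psf_fwhm_mm <= 0) stop("system_model: psf_fwhm_mm must be > 0")
  if (count_scale <= 0) stop("system_model: count_scale must be > 0")
  if (any(attenuation$values <= 0) || any(attenuation$values > 1))
    stop("system_model: attenuation factors must lie in (0, 1]")
  if (is.null(scatter))
    scatter <- sino_like(attenuation, array(0, dim(attenuation$values)))
  if (is.null(normalization))
    normalization <- sino_like(attenuation, array(1, dim(attenuation$values)))
  stopifnot_same_geometry(attenuation, scatter)
  stopifnot_same_geometry(attenuation, normalization)
  if (any(normalization$values <= 0))
    stop("system_model: normalization must be > 0")
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  structure(list(psf_fwhm_mm = psf_fwhm_mm, attenuation = attenuation,
                 scatter = scatter, normalization = normalization,
                 count_scale = count_scale, img_dim = as.integer(img_dim),
                 voxel_size_mm = voxel_size_mm,
                 angles = attenuation$angles,
                 n_radial = dim(attenuation$values)[2],
                 radial_bin_mm = attenuation$radial_bin_mm),
            class = "system_model")
}

#' @export
print.system_model <- function(x, ...) {
  cat(sprintf("<system_model> PSF %.3g mm FWHM, %d angles x %d radial, count_scale %.4g\n",
              x$psf_fwhm_mm, length(x$angles), x$n_radial, x$count_scale))
  cat(sprintf("  attenuation range [%.3g, %.3g], scatter total %.4g\n",
              min(x$attenuation$values), max(x$attenuation$values),
              sum(x$scatter$values)))
  invisible(x)
}

blur_image <- function(values, fwhm_mm, voxel_size_mm) {
  if (fwhm_mm <= 0) return(values)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / rep_len(voxel_size_mm, 3L)
  cpp_gauss_blur3(values, dim(values), sigma)
}

#' Per-bin attenuation factors from an attenuation map
#'
#' Computes `exp(-integral of mu along the bin's line)` for every sinogram
#' bin by ray-transforming the attenuation map.
#'
#' @param mu `image_volume` with role `"mu"` (mm^-1, >= 0).
#' @param geometry a [projection_geometry()].
#' @return A `sinogram` of factors in (0, 1].
#' @export
compute_attenuation_factors <- function(mu, geometry = NULL) {
  if (!is_image_volume(mu) || mu$role != "mu")
    stop("compute_attenuation_factors: `mu` must be an image_volume with role 'mu'")
  if (any(mu$values < 0)) stop("compute_attenuation_factors: negative mu")
  if (is.null(geometry))
    geometry <- projection_geometry(dim(mu$values), mu$voxel_size_mm)
  vox <- mu$voxel_size_mm[1]
  raw <- cpp_ray_forward(mu$values, dim(mu$values), geometry$angles,
                         geometry$n_radial, vox, geometry$radial_bin_mm)
  # splat sums approximate the line integral after scaling by the in-plane
  # voxel area over the bin width
  line_int <- raw * vox^2 / geometry$radial_bin_mm
  sinogram(exp(-line_int), geometry$angles, geometry$radial_bin_mm)
}

#' Forward-project an activity volume
#'
#' Applies the image-space Gaussian PSF, the slice-wise parallel-beam ray
#' transform, the count scale, per-bin normalization and attenuation, and
#' (optionally) adds the model's scatter expectation:
#' `lambda = n * a * scale * Ray(PSF (*) x) + s`. Linear in the activity
#' when scatter is held fixed.
#'
#' @param activity `image_volume` of activity (kBq/mL).
#' @param model a [system_model()].
#' @param subset optional integer vector of angle indices (an OSEM subset);
#'   default all angles.
#' @param include_scatter add the model's additive scatter term.
#' @param psf apply the PSF (`TRUE` by default); `psf_fwhm_mm` overrides the
#'   model's width (used for resolution modeling during reconstruction).
#' @param psf_fwhm_mm PSF width override, mm.
#' @return A `sinogram` of expectations (subset angles only if `subset`).
#' @export
forward_project <- function(activity, model, subset = NULL,
                            include_scatter = TRUE, psf = TRUE,
                            psf_fwhm_mm = model$psf_fwhm_mm) {
  if (!identical(dim(activity$values), model$img_dim))
    stop("forward_project: image / model grid mismatch")
  if (is.null(subset)) subset <- seq_along(model$angles)
  x <- activity$values
  if (psf) x <- blur_image(x, psf_fwhm_mm, model$voxel_size_mm)
  raw <- cpp_ray_forward(x, dim(x), model$angles[subset], model$n_radial,
                         model$voxel_size_mm[1], model$radial_bin_mm)
  scale <- model$count_scale / length(model$angles) * prod(model$voxel_size_mm)
  lam <- model$normalization$values[subset, , , drop = FALSE] *
    model$attenuation$values[subset, , , drop = FALSE] * scale * raw
  if (include_scatter)
    lam <- lam + model$scatter$values[subset, , , drop = FALSE]
  sinogram(lam, model$angles[subset], model$radial_bin_mm)
}

#' Back-project a sinogram (exact adjoint of the projector)
#'
#' Adjoint of [forward_project()] with scatter excluded: weights the bins by
#' normalization, attenuation and count scale, applies the transpose ray
#' transform and the (self-adjoint) PSF.
#'
#' @param sino a `sinogram`; may cover an angle subset (pass `subset`).
#' @param model a [system_model()].
#' @param subset integer angle indices matching `sino`'s first dimension.
#' @param psf,psf_fwhm_mm as in [forward_project()].
#' @return An `image_volume` (role `"activity"`).
#' @export
back_project <- function(sino, model, subset = NULL, psf = TRUE,
                         psf_fwhm_mm = model$psf_fwhm_mm) {
  if (is.null(subset)) subset <- seq_along(model$angles)
  if (dim(sino$values)[1] != length(subset))
    stop("back_project: sinogram / subset geometry mismatch")
  scale <- model$count_scale / length(model$angles) * prod(model$voxel_size_mm)
  w <- model$normalization$values[subset, , , drop = FALSE] *
    model$attenuation$values[subset, , , drop = FALSE] * scale * sino$values
  img <- cpp_ray_back(w, dim(w), model$angles[subset], model$img_dim,
                      model$voxel_size_mm[1], model$radial_bin_mm)
  if (psf) img <- blur_image(img, psf_fwhm_mm, model$voxel_size_mm)
  # the adjoint of a linear map may be applied to signed data, so skip the
  # non-negativity check of the public constructor
  structure(list(values = img, voxel_size_mm = model$voxel_size_mm,
                 origin_mm = -(model$img_dim - 1) / 2 * model$voxel_size_mm,
                 role = "activity"), class = "image_volume")
}

#' Additive scatter estimate (convolution-fraction model)
#'
#' Models scatter as a strongly smoothed copy of the unscattered trues: the
#' trues sinogram is convolved with a wide Gaussian along the radial and
#' axial directions and rescaled so that the scatter total equals
#' `SF / (1 - SF)` times the trues total (SF = scatter fraction). This
#' reproduces the two properties the correction chain relies on — an
#' additive, non-negative, smooth sinogram term of controlled magnitude.
#'
#' @param emission_estimate `image_volume` of the emission distribution.
#' @param model a [system_model()] (attenuation/geometry source).
#' @param scatter_fraction scatter fraction SF in `[0, 1)`.
#' @param kernel_fwhm_mm width of the smoothing kernel, mm (default 80).
#' @return A `sinogram` of scatter expectations.
#' @export
estimate_scatter <- function(emission_estimate, model, scatter_fraction,
                             kernel_fwhm_mm = 80) {
  if (scatter_fraction < 0 || scatter_fraction >= 1)
    stop("estimate_scatter: scatter fraction must lie in [0, 1)")
  trues <- forward_project(emission_estimate, model, include_scatter = FALSE)
  scatter_from_trues(trues, scatter_fraction, kernel_fwhm_mm)
}

scatter_from_trues <- function(trues, scatter_fraction, kernel_fwhm_mm = 80) {
  if (scatter_fraction == 0)
    return(sino_like(trues, array(0, dim(trues$values))))
  sig_r <- kernel_fwhm_mm / (2 * sqrt(2 * log(2))) / trues$radial_bin_mm
  sm <- cpp_gauss_blur3(trues$values, dim(trues$values), c(0, sig_r, sig_r / 2))
  tot <- sum(trues$values)
  target <- scatter_fraction / (1 - scatter_fraction) * tot
  s <- if (sum(sm) > 0) sm * target / sum(sm) else sm
  sino_like(trues, s)
}

#' Draw Poisson counts from a sinogram of expectations
#'
#' @param expectations `sinogram` of non-negative expectations.
#' @param seed integer seed (reproducible draw).
#' @return A `sinogram` with `counts_flag = TRUE`.
#' @export
add_poisson_noise <- function(expectations, seed) {
  if (any(expectations$values < 0))
    stop("add_poisson_noise: negative expectation")
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  counts <- array(rpois(length(expectations$values), expectations$values),
                  dim(expectations$values))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  sino_like(expectations, counts, counts_flag = TRUE, seed = as.integer(seed))
}

#' Simulate a full acquisition of a phantom
#'
#' Builds the attenuation factors from the phantom's mu map, calibrates the
#' count scale so the expected total (trues + scatter) matches
#' `total_counts`, forms the scatter estimate from the trues, and draws
#' Poisson counts.
#'
#' @param phantom a `phantom` from [build_phantom()].
#' @param psf_fwhm_mm acquisition PSF width, mm.
#' @param scatter_fraction scatter fraction in `[0, 1)`.
#' @param total_counts expected total detected counts.
#' @param n_angles number of views.
#' @param seed integer seed for the Poisson draw.
#' @param noise draw Poisson counts (`TRUE`) or return noise-free
#'   expectations rounded into the counts slot (`FALSE`).
#' @return List with `counts`, `expectations` (`sinogram`s) and `model`
#'   (a [system_model()] whose scatter slot holds the estimate used).
#' @export
simulate_acquisition <- function(phantom, psf_fwhm_mm = 4,
                                 scatter_fraction = 0.2,
                                 total_counts = 1e6, n_angles = 120L,
                                 seed = 1L, noise = TRUE) {
  geom <- projection_geometry(dim(phantom$activity$values),
                              phantom$activity$voxel_size_mm, n_angles)
  att <- compute_attenuation_factors(phantom$mu, geom)
  model1 <- system_model(psf_fwhm_mm, att, count_scale = 1,
                         img_dim = dim(phantom$activity$values),
                         voxel_size_mm = phantom$activity$voxel_size_mm)
  trues1 <- forward_project(phantom$activity, model1, include_scatter = FALSE)
  count_scale <- total_counts * (1 - scatter_fraction) / sum(trues1$values)
  trues <- sino_like(trues1, trues1$values * count_scale)
  scatter <- scatter_from_trues(trues, scatter_fraction)
  model <- system_model(psf_fwhm_mm, att, scatter = scatter,
                        count_scale = count_scale,
                        img_dim = dim(phantom$activity$values),
                        voxel_size_mm = phantom$activity$voxel_size_mm)
  expectations <- sino_like(trues, trues$values + scatter$values)
  counts <- if (noise) add_poisson_noise(expectations, seed)
            else sino_like(expectations, expectations$values, seed = as.integer(seed))
  list(counts = counts, expectations = expectations, model = model,
       seed = as.integer(seed))
}
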