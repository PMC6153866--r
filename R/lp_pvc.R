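# The local-projection (LP) partial-volume correction. Tissues inside a
# small VOI are segmented (CT threshold or PET half-max isocontour), each
# tissue's unit-activity, resolution-blurred, attenuated projection P_ij is
# computed, and the per-tissue activities A_j are fitted to the measured
# counts through the linear model
#     lambda_i = sum_j A_j P_ij + g_out_i
# where g_out is the projection of everything outside the VOI (plus
# scatter), held fixed. The fitted activities are substituted into the
# image, which is re-projected with full physics and re-reconstructed to
# give the corrected image.

#' CT threshold segmentation of a calcified lesion
#'
#' Selects voxels above an HU threshold inside a search region and keeps the
#' largest connected component (face connectivity).
#'
#' @param hu `image_volume` with role `"hu"`.
#' @param search_region optional logical array restricting the search.
#' @param threshold_hu HU threshold (default 110, the calcification
#'   threshold for low-dose CT).
#' @return Logical lesion mask (3D array).
#' @export
segment_ct_threshold <- function(hu, search_region = NULL, threshold_hu = 110) {
  if (!is_image_volume(hu) || hu$role != "hu")
    stop("segment_ct_threshold: `hu` must be an image_volume with role 'hu'")
  m <- hu$values > threshold_hu
  if (!is.null(search_region)) m <- m & search_region
  if (!any(m)) stop("segment_ct_threshold: no calcified voxels above threshold")
  lab <- cpp_label_components(m, dim(m), 6L)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

#' PET half-max isocontour segmentation adapted to background
#'
#' 3D isocontour halfway between the maximum voxel activity in the search
#' region and the mean background activity: voxels with
#' `value >= (max + background) / 2` connected (face connectivity) to the
#' maximum voxel.
#'
#' @param pet `image_volume` of reconstructed activity.
#' @param search_region optional logical array restricting where the maximum
#'   is looked up.
#' @param background_mean mean background activity (kBq/mL, >= 0).
#' @return Logical lesion mask (3D array).
#' @export
segment_pet_halfmax <- function(pet, search_region = NULL, background_mean) {
  if (background_mean < 0) stop("segment_pet_halfmax: background must be >= 0")
  v <- pet$values
  look <- if (is.null(search_region)) array(TRUE, dim(v)) else search_region
  mx <- max(v[look])
  if (mx <= background_mean)
    stop("segment_pet_halfmax: lesion not distinguishable from background")
  thr <- (mx + background_mean) / 2
  m <- v >= thr
  lab <- cpp_label_components(m, dim(v), 6L)
  idx <- which(look & v == mx)[1]
  lab == lab[idx]
}

#' Define the local VOI and its tissue partition
#'
#' The VOI is the lesion mask dilated by a Euclidean margin. Tissue 1 is the
#' lesion; optional extra tissue masks (e.g. a separate calcification) get
#' the next labels; the remaining VOI voxels form the local background
#' tissue. With `margin_mm = 0` and no extras the VOI is the lesion alone
#' (J = 1).
#'
#' @param lesion_mask logical 3D array (non-empty).
#' @param voxel_size_mm voxel size, mm.
#' @param margin_mm dilation margin, mm (default 12, about 1.5 times the
#'   widest clinical PSF, trading locality against background estimation).
#' @param extra_tissues optional named list of logical masks.
#' @param restrict optional logical mask (e.g. the body contour from CT)
#'   the dilated VOI is intersected with, so the local-background tissue is
#'   not diluted by out-of-body voxels; the lesion itself is always kept.
#' @return An object of class `local_voi`: list with `mask`, integer
#'   `labels` (0 outside the VOI), `J`, `tissue_names`, `voxel_size_mm`.
#' @export
define_local_voi <- function(lesion_mask, voxel_size_mm, margin_mm = 12,
                             extra_tissues = NULL, restrict = NULL) {
  if (!any(lesion_mask)) stop("define_local_voi: empty lesion mask")
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  d <- dim(lesion_mask)
  voi <- lesion_mask
  if (margin_mm > 0) {
    r <- ceiling(margin_mm / voxel_size_mm)
    off <- as.matrix(expand.grid(x = -r[1]:r[1], y = -r[2]:r[2], z = -r[3]:r[3]))
    keep <- (off[, 1] * voxel_size_mm[1])^2 + (off[, 2] * voxel_size_mm[2])^2 +
      (off[, 3] * voxel_size_mm[3])^2 <= margin_mm^2
    voi <- cpp_dilate_mask(lesion_mask, d, off[keep, , drop = FALSE])
  }
  for (m in extra_tissues) voi <- voi | m
  if (!is.null(restrict)) voi <- (voi & restrict) | lesion_mask

  edge <- array(FALSE, d)
  edge[c(1, d[1]), , ] <- TRUE; edge[, c(1, d[2]), ] <- TRUE; edge[, , c(1, d[3])] <- TRUE
  if (any(voi & edge)) stop("define_local_voi: VOI touches the grid boundary")

  labels <- array(0L, d)
  labels[lesion_mask] <- 1L
  nm <- "lesion"
  nxt <- 2L
  for (k in seq_along(extra_tissues)) {
    m <- extra_tissues[[k]] & voi & labels == 0L
    if (any(m)) {
      labels[m] <- nxt
      nm <- c(nm, if (!is.null(names(extra_tissues)[k]) && nzchar(names(extra_tissues)[k]))
        names(extra_tissues)[k] else sprintf("tissue_%d", nxt))
      nxt <- nxt + 1L
    }
  }
  shell <- voi & labels == 0L
  if (any(shell)) {
    labels[shell] <- nxt
    nm <- c(nm, "background")
  }
  structure(list(mask = voi, labels = labels, J = length(nm),
                 tissue_names = nm, voxel_size_mm = voxel_size_mm),
            class = "local_voi")
}

#' @export
print.local_voi <- function(x, ...) {
  cat(sprintf("<local_voi> %d voxels, J = %d tissues (%s)\n",
              sum(x$mask), x$J, paste(x$tissue_names, collapse = ", ")))
  invisible(x)
}

#' Unit-activity tissue projections P_ij
#'
#' Forward-projects the indicator of each VOI tissue with the full system
#' model (PSF, attenuation, normalization; no scatter), yielding the
#' resolution-blurred tissue shape functions of the LP model, together with
#' the support mask of sinogram bins whose rays intersect the VOI.
#'
#' @param voi a [define_local_voi()] result.
#' @param model a [system_model()].
#' @return An object of class `tissue_projection_set`: list with `P` (one
#'   sinogram-shaped array per tissue), `support` (logical array), the
#'   tissue names and the VOI.
#' @export
compute_tissue_projections <- function(voi, model) {
  stopifnot(inherits(voi, "local_voi"))
  P <- vector("list", voi$J)
  for (j in seq_len(voi$J)) {
    ind <- voi$labels == j
    if (!any(ind)) stop(sprintf("compute_tissue_projections: empty tissue %d", j))
    P[[j]] <- forward_project(image_volume(ind * 1, model$voxel_size_mm),
                              model, include_scatter = FALSE)$values
  }
  total <- Reduce(`+`, P)
  support <- total > 1e-12 * max(total)
  structure(list(P = P, support = support, tissue_names = voi$tissue_names,
                 voi = voi), class = "tissue_projection_set")
}

#' Outside-VOI background projection g_out
#'
#' Forward-projects the current reconstructed image with the VOI voxels set
#' to zero (full physics) and adds the model's scatter expectation: the
#' per-bin counts attributable to everything outside the VOI, held fixed
#' during the LP fit.
#'
#' @param recon_image current reconstructed `image_volume`.
#' @param voi a [define_local_voi()] result.
#' @param model a [system_model()].
#' @return A `sinogram`.
#' @export
estimate_outside_background <- function(recon_image, voi, model) {
  out <- recon_image$values
  out[voi$mask] <- 0
  forward_project(image_volume(out, model$voxel_size_mm), model,
                  include_scatter = TRUE)
}

#' Fit the LP tissue activities
#'
#' Weighted least-squares fit of the linear model
#' `y_i = g_out_i + sum_j A_j P_ij` on the support bins. Weights follow the
#' Poisson variance of the *model* counts via one reweighting pass: an
#' ordinary least-squares fit provides fitted expectations, and the final
#' estimate uses `w_i = 1 / max(lambda_hat_i, 1)`. (Weighting by the
#' measured counts instead is badly biased in the few-counts-per-bin
#' regime, where downward fluctuations would be over-trusted.) Activities
#' are optionally constrained non-negative (default on). Exact in the
#' noise-free matched-model limit.
#'
#' @param counts `sinogram` of measured counts.
#' @param tps a [compute_tissue_projections()] result.
#' @param g_out `sinogram` from [estimate_outside_background()].
#' @param nonneg constrain activities to be >= 0.
#' @return An object of class `lp_fit`: named `activities` (kBq/mL),
#'   `activity_covariance`, `residual_norm`, `model_counts` (`sinogram`),
#'   `g_out`, `support`, and the VOI.
#' @export
fit_lp_activities <- function(counts, tps, g_out, nonneg = TRUE) {
  stopifnot(inherits(tps, "tissue_projection_set"))
  sup <- tps$support
  if (!any(sup)) stop("fit_lp_activities: empty support")
  J <- length(tps$P)
  if (J > sum(sup)) stop("fit_lp_activities: more tissues than support bins")
  X <- vapply(tps$P, function(p) p[sup], numeric(sum(sup)))
  y <- counts$values[sup]
  g <- g_out$values[sup]
  if (J >= 2) {
    cc <- suppressWarnings(cor(X))
    diag(cc) <- 0
    if (any(!is.finite(cc)) || any(abs(cc) > 0.999))
      stop("fit_lp_activities: degenerate tissue projections")
  }
  solve_wls <- function(w) {
    Xw <- X * sqrt(w)
    bw <- (y - g) * sqrt(w)
    xtx <- crossprod(Xw)
    if (rcond(xtx) < 1e-12) stop("fit_lp_activities: degenerate tissue projections")
    A <- drop(solve(xtx, crossprod(Xw, bw)))
    if (nonneg && any(A < 0)) A <- pracma::lsqnonneg(Xw, bw)$x
    list(A = A, xtx = xtx)
  }
  A0 <- solve_wls(rep(1, length(y)))$A
  w <- 1 / pmax(g + drop(X %*% A0), 1)
  sol <- solve_wls(w)
  A <- sol$A
  xtx <- sol$xtx
  names(A) <- tps$tissue_names
  fitted_vals <- Reduce(`+`, Map(function(p, a) p * a, tps$P, as.list(A))) +
    g_out$values
  resid <- y - g - drop(X %*% A)
  structure(list(activities = A,
                 activity_covariance = solve(xtx),
                 residual_norm = sqrt(sum(w * resid^2)),
                 model_counts = sino_like(g_out, pmax(fitted_vals, 0)),
                 g_out = g_out, support = sup, voi = tps$voi,
                 nonneg = nonneg),
            class = "lp_fit")
}

#' @export
print.lp_fit <- function(x, ...) {
  cat("<lp_fit> tissue activities (kBq/mL):\n")
  print(round(x$activities, 4))
  cat(sprintf("  residual norm %.4g on %d support bins\n",
              x$residual_norm, sum(x$support)))
  invisible(x)
}

#' Lesion-to-background ratio of the fitted LP activities
#'
#' Ratio of the fitted lesion activity over the fitted local-background
#' activity (or over a supplied background mean when the VOI has no
#' background tissue, e.g. a zero-margin VOI).
#'
#' @param fit an [fit_lp_activities()] result.
#' @param background_mean fallback background activity (kBq/mL).
#' @return The LP activity ratio.
#' @export
lp_ratio <- function(fit, background_mean = NULL) {
  stopifnot(inherits(fit, "lp_fit"))
  A <- fit$activities
  bg <- if ("background" %in% names(A)) unname(A["background"]) else background_mean
  if (is.null(bg)) stop("lp_ratio: no background tissue; supply background_mean")
  if (bg <= 0) stop("lp_ratio: non-positive background activity")
  unname(A["lesion"]) / bg
}

#' Substitute the fitted tissue activities into an image
#'
#' Every VOI voxel of tissue j is set to A_j; all voxels outside the VOI
#' are left bit-identical to the input.
#'
#' @param image an `image_volume`.
#' @param voi a [define_local_voi()] result.
#' @param fit an [fit_lp_activities()] result (or a numeric vector of
#'   per-tissue activities).
#' @return The substituted `image_volume`.
#' @export
substitute_voi <- function(image, voi, fit) {
  A <- if (inherits(fit, "lp_fit")) fit$activities else fit
  if (length(A) != voi$J) stop("substitute_voi: one activity per tissue required")
  v <- image$values
  for (j in seq_len(voi$J)) v[voi$labels == j] <- A[j]
  with_values(image, v)
}

resolve_segmentation <- function(segmentation, recon_image) {
  if (is.logical(segmentation) && is.array(segmentation)) return(segmentation)
  stopifnot(is.list(segmentation))
  mode <- segmentation$mode
  if (identical(mode, "ct"))
    segment_ct_threshold(segmentation$hu, segmentation$search_region,
                         if (is.null(segmentation$threshold_hu)) 110 else segmentation$threshold_hu)
  else if (identical(mode, "pet"))
    segment_pet_halfmax(recon_image, segmentation$search_region,
                        segmentation$background_mean)
  else if (identical(mode, "mask")) segmentation$mask
  else stop("unknown segmentation mode")
}

lp_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("lp_pvc [%s]: %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the full LP partial-volume correction
#'
#' Executes the whole chain: segment the lesion, build the local VOI,
#' compute the tissue projections and the outside background, fit the LP
#' activities, substitute them into the image, re-project with full physics
#' (attenuation, scatter, optional Poisson noise) and re-reconstruct with
#' OSEM. The LP activities are not altered by the final reconstruction.
#'
#' @param counts measured `sinogram`.
#' @param recon_image uncorrected reconstructed `image_volume`.
#' @param model a [system_model()].
#' @param segmentation a logical lesion mask, or a list: `list(mode = "ct",
#'   hu =, threshold_hu =, search_region =)`, `list(mode = "pet",
#'   background_mean =, search_region =)` or `list(mode = "mask", mask =)`.
#' @param margin_mm VOI dilation margin, mm.
#' @param extra_tissues optional named list of extra tissue masks.
#' @param restrict optional body-contour mask for the VOI (see
#'   [define_local_voi()]).
#' @param g_out_image optional low-noise `image_volume` used for the
#'   outside-background estimate instead of `recon_image` (e.g. a lightly
#'   iterated, smoothed companion reconstruction); `NULL` uses
#'   `recon_image`.
#' @param recon_cfg [recon_config()] for the final reconstruction (default
#'   5 iterations, 21 subsets).
#' @param noise add Poisson noise to the re-projected data (default TRUE).
#' @param seed seed for the re-projection noise.
#' @param nonneg non-negativity of the fitted activities.
#' @return An object of class `pvc_result`: `lp_fit`, `voi`,
#'   `substituted_image`, `pvc_sinogram`, `pvc_image`, `config`.
#' @export
run_lp_pvc <- function(counts, recon_image, model, segmentation,
                       margin_mm = 12, extra_tissues = NULL, restrict = NULL,
                       g_out_image = NULL, recon_cfg = recon_config(),
                       noise = TRUE, seed = 1L, nonneg = TRUE) {
  mask <- lp_stage("segment", resolve_segmentation(segmentation, recon_image))
  voi <- lp_stage("voi", define_local_voi(mask, model$voxel_size_mm, margin_mm,
                                          extra_tissues, restrict))
  tps <- lp_stage("projections", compute_tissue_projections(voi, model))
  if (is.null(g_out_image)) g_out_image <- recon_image
  g_out <- lp_stage("projections",
                    estimate_outside_background(g_out_image, voi, model))
  fit <- lp_stage("fit", fit_lp_activities(counts, tps, g_out, nonneg))
  sub_img <- lp_stage("substitute", substitute_voi(recon_image, voi, fit))
  sino <- lp_stage("reproject", {
    expect <- forward_project(sub_img, model, include_scatter = TRUE)
    if (noise) add_poisson_noise(expect, seed) else expect
  })
  pvc_img <- lp_stage("recon", osem(sino, model, recon_cfg))
  structure(list(lp_fit = fit, voi = voi, substituted_image = sub_img,
                 pvc_sinogram = sino, pvc_image = pvc_img,
                 config = list(margin_mm = margin_mm, recon_cfg = recon_cfg,
                               noise = noise, seed = as.integer(seed),
                               nonneg = nonneg)),
            class = "pvc_result")
}

#' @export
print.pvc_result <- function(x, ...) {
  cat("<pvc_result>\n")
  print(x$lp_fit)
  invisible(x)
}

#' Calibrate the PSF FWHM from a large-sphere acquisition
#'
#' Scans the assumed Gaussian PSF width and returns the value at which the
#' LP-fitted lesion-to-background ratio of a large (>= 30 mm) sphere of
#' known true ratio matches that ratio, by bounded scalar minimisation of
#' the absolute ratio error. For each candidate width the outside
#' background is estimated from a short resolution-modeled reconstruction
#' under that same width, so that masking and re-blurring the activity
#' estimate remain consistent (an image reconstructed *without* resolution
#' modeling is itself blurred, and re-blurring it under-counts the
#' background spill across the VOI boundary — noticeably so for wide
#' PSFs).
#'
#' @param counts measured `sinogram` of the calibration phantom.
#' @param recon_image optional reconstructed `image_volume` used for the
#'   outside-background estimate when `psf_recon_g_out = FALSE`.
#' @param model a [system_model()] (its PSF width is ignored and scanned).
#' @param lesion_mask logical mask of the calibration sphere.
#' @param background_mean background activity for the ratio when the VOI
#'   has no background tissue (kBq/mL); usually `NULL` (fitted shell used).
#' @param true_ratio known true lesion-to-background ratio.
#' @param bounds search bounds for the FWHM, mm.
#' @param margin_mm VOI margin, mm.
#' @param tol search tolerance, mm (default 0.1).
#' @param restrict optional body-contour mask for the VOI.
#' @param psf_recon_g_out estimate the outside background from a 2-iteration
#'   resolution-modeled reconstruction at each candidate width (default);
#'   `FALSE` uses `recon_image` as-is.
#' @param g_smooth_fwhm_mm optional smoothing of that companion
#'   reconstruction, mm (for noisy data).
#' @return List with `fwhm_mm`, the achieved `ratio` and the `objective`.
#' @export
calibrate_fwhm <- function(counts, recon_image = NULL, model, lesion_mask,
                           background_mean = NULL, true_ratio, bounds = c(1, 12),
                           margin_mm = 12, tol = 0.1, restrict = NULL,
                           psf_recon_g_out = TRUE, g_smooth_fwhm_mm = 0) {
  voi <- define_local_voi(lesion_mask, model$voxel_size_mm, margin_mm,
                          restrict = restrict)
  if (!psf_recon_g_out && is.null(recon_image))
    stop("calibrate_fwhm: recon_image required when psf_recon_g_out = FALSE")
  ratio_at <- function(f) {
    m <- model
    m$psf_fwhm_mm <- f
    g_img <- if (psf_recon_g_out) {
      ns <- min(21L, length(m$angles))
      gaussian_postfilter(osem(counts, m, recon_config(2L, ns, psf_in_recon = TRUE)),
                          g_smooth_fwhm_mm)
    } else recon_image
    tps <- compute_tissue_projections(voi, m)
    g_out <- estimate_outside_background(g_img, voi, m)
    lp_ratio(fit_lp_activities(counts, tps, g_out), background_mean)
  }
  obj <- function(f) abs(ratio_at(f) - true_ratio)
  opt <- optimize(obj, interval = bounds, tol = tol)
  if (min(opt$minimum - bounds[1], bounds[2] - opt$minimum) < 2 * tol)
    stop("calibrate_fwhm: no minimum inside bounds")
  list(fwhm_mm = opt$minimum, objective = opt$objective,
       ratio = ratio_at(opt$minimum))
}
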