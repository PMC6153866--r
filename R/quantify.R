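# Figures of merit and statistics: lesion-to-background ratios (max, mean,
# A50 isocontour), their relative change after correction, plaque HU
# classification, hyperbolic trend fits y = A/x + B, and the association
# statistics (Pearson, Spearman, one-sided paired t).

#' Maximum-voxel lesion-to-background ratio
#'
#' @param img an `image_volume`.
#' @param lesion_mask logical array selecting the lesion.
#' @param background_mask logical array of uniform background regions.
#' @return `max(img | lesion) / mean(img | background)`.
#' @export
lbr_max <- function(img, lesion_mask, background_mask) {
  bg <- mean(img$values[background_mask])
  if (!is.finite(bg) || bg <= 0) stop("lbr_max: background mean must be > 0")
  max(img$values[lesion_mask]) / bg
}

#' Mean lesion-to-background ratio over a segmentation mask
#'
#' @inheritParams lbr_max
#' @return `mean(img | lesion) / mean(img | background)`.
#' @export
lbr_mean <- function(img, lesion_mask, background_mask) {
  bg <- mean(img$values[background_mask])
  if (!is.finite(bg) || bg <= 0) stop("lbr_mean: background mean must be > 0")
  mean(img$values[lesion_mask]) / bg
}

#' A50 lesion-to-background ratio
#'
#' Mean activity inside the 3D isocontour at 50% of the maximum voxel
#' activity adapted to the mean background (threshold `(max + bg)/2`,
#' face-connected to the maximum voxel), divided by the background mean.
#'
#' @param img an `image_volume`.
#' @param lesion_mask logical array locating the lesion (where the maximum
#'   is looked up).
#' @param background_mean mean background activity (> 0).
#' @return The A50 ratio.
#' @export
lbr_a50 <- function(img, lesion_mask, background_mean) {
  if (background_mean <= 0) stop("lbr_a50: background mean must be > 0")
  v <- img$values
  mx <- max(v[lesion_mask])
  thr <- (mx + background_mean) / 2
  m <- v >= thr
  lab <- cpp_label_components(m, dim(v), 6L)
  idx <- which(lesion_mask & v == mx)[1]
  iso <- lab == lab[idx]
  mean(v[iso]) / background_mean
}

#' Relative change of the lesion-to-background ratio
#'
#' `delta = (LBR_pvc - LBR_nopvc) / LBR_nopvc * 100` (percent, signed).
#'
#' @param lbr_pvc ratio after correction.
#' @param lbr_nopvc ratio before correction (> 0).
#' @return Percent change.
#' @export
delta_lbr <- function(lbr_pvc, lbr_nopvc) {
  if (any(lbr_nopvc <= 0)) stop("delta_lbr: uncorrected ratio must be > 0")
  (lbr_pvc - lbr_nopvc) / lbr_nopvc * 100
}

#' Plaque classification by maximum HU
#'
#' Four classes: non-calcified (HU < 110), light (110 <= HU < 210), medium
#' (210 <= HU < 550) and heavy (HU >= 550). A density of at least 110 HU
#' defines calcification, so the 110 boundary is assigned to the light
#' class.
#'
#' @param hu_max maximum HU within the plaque (finite; vectorised).
#' @return Factor with levels `non_calcified`, `light`, `medium`, `heavy`.
#' @export
classify_plaque <- function(hu_max) {
  if (any(!is.finite(hu_max))) stop("classify_plaque: HU must be finite")
  cut(hu_max, breaks = c(-Inf, 110, 210, 550, Inf), right = FALSE,
      labels = c("non_calcified", "light", "medium", "heavy"))
}

#' Hyperbolic trend fit y = A/x + B
#'
#' Ordinary least squares in the transformed regressor 1/x, with standard
#' errors, plus the Pearson and Spearman correlations of the untransformed
#' pair (x, y).
#'
#' @param x positive predictor (volume in mm^3 or density in HU).
#' @param y response (LBR or delta-LBR).
#' @return Object of class `hyperbolic_fit`: `A`, `B`, `A_se`, `B_se`,
#'   `pearson_r`, `spearman_s`, `n`.
#' @export
fit_hyperbolic <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("fit_hyperbolic: need at least 3 (x, y) pairs")
  if (any(x <= 0)) stop("fit_hyperbolic: all x must be > 0")
  if (sd(x) == 0) stop("fit_hyperbolic: degenerate x (all equal)")
  fit <- lm(y ~ I(1 / x))
  cf <- coef(fit)
  # an exactly hyperbolic input is a perfect fit; its zero residual warning
  # from summary.lm is expected, not a problem
  se <- suppressWarnings(sqrt(diag(vcov(fit))))
  # a constant response has no defined correlation; report NA, not a warning
  safe_cor <- function(...) if (sd(y) == 0) NA_real_ else cor(...)
  structure(list(A = unname(cf[2]), B = unname(cf[1]),
                 A_se = unname(se[2]), B_se = unname(se[1]),
                 pearson_r = safe_cor(x, y),
                 spearman_s = safe_cor(x, y, method = "spearman"),
                 n = length(x)),
            class = "hyperbolic_fit")
}

#' @export
print.hyperbolic_fit <- function(x, ...) {
  cat(sprintf("<hyperbolic_fit> y = A/x + B: A = %.4g +/- %.3g, B = %.4g +/- %.3g\n",
              x$A, x$A_se, x$B, x$B_se))
  cat(sprintf("  Pearson r = %.3f, Spearman s = %.3f, n = %d\n",
              x$pearson_r, x$spearman_s, x$n))
  invisible(x)
}

#' Association statistics for paired measurements
#'
#' Pearson and Spearman correlations plus a one-sided paired t test of
#' `corrected > uncorrected` (df = n - 1). Identical samples give t = 0 and
#' p = 0.5; a constant non-zero difference has no variance and errors.
#'
#' @param corrected,uncorrected paired numeric vectors (n >= 3).
#' @return List with `pearson`, `spearman`, `t`, `df`, `p_one_sided`.
#' @export
association_stats <- function(corrected, uncorrected) {
  n <- length(corrected)
  if (length(uncorrected) != n || n < 3)
    stop("association_stats: need >= 3 pairs")
  if (sd(corrected) == 0 || sd(uncorrected) == 0)
    stop("association_stats: zero variance sample")
  d <- corrected - uncorrected
  if (all(d == 0)) {
    tt <- 0; p <- 0.5
  } else if (sd(d) == 0) {
    stop("association_stats: zero variance of paired differences")
  } else {
    tt <- mean(d) / (sd(d) / sqrt(n))
    p <- pt(tt, df = n - 1, lower.tail = FALSE)
  }
  list(pearson = cor(corrected, uncorrected),
       spearman = cor(corrected, uncorrected, method = "spearman"),
       t = tt, df = n - 1, p_one_sided = p)
}

#' Deterministic background VOIs in lesion-free body regions
#'
#' Places `n` spherical VOIs of the given diameter fully inside the body
#' mask and away from all lesions, scanning candidate centres in a fixed
#' raster order (deterministic for a fixed phantom).
#'
#' @param body logical in-body mask.
#' @param voxel_size_mm voxel size, mm.
#' @param exclude logical mask of regions to stay clear of (lesions), or
#'   `NULL`.
#' @param n number of VOIs (default 3).
#' @param diameter_mm VOI diameter, mm (default 15).
#' @param clearance_mm minimum distance between a VOI surface and the
#'   exclusion mask or body edge, mm.
#' @return Logical mask of the union of the VOIs (attribute `centers`
#'   holds the voxel-index centres).
#' @export
background_vois <- function(body, voxel_size_mm, exclude = NULL, n = 3,
                            diameter_mm = 15, clearance_mm = 10) {
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  d <- dim(body)
  r <- (diameter_mm / 2 + clearance_mm) / voxel_size_mm
  rr <- ceiling(r)
  off <- as.matrix(expand.grid(x = -rr[1]:rr[1], y = -rr[2]:rr[2], z = -rr[3]:rr[3]))
  dist2 <- (off[, 1] * voxel_size_mm[1])^2 + (off[, 2] * voxel_size_mm[2])^2 +
    (off[, 3] * voxel_size_mm[3])^2
  off_voi <- off[dist2 <= (diameter_mm / 2)^2, , drop = FALSE]
  off_chk <- off[dist2 <= (diameter_mm / 2 + clearance_mm)^2, , drop = FALSE]
  step <- pmax(1L, floor(diameter_mm / voxel_size_mm / 2))
  out <- array(FALSE, d)
  centers <- NULL
  placed <- 0L
  taken <- array(FALSE, d)
  for (k in seq(1 + rr[3], d[3] - rr[3], by = step[3])) {
    for (j in seq(1 + rr[2], d[2] - rr[2], by = step[2])) {
      for (i in seq(1 + rr[1], d[1] - rr[1], by = step[1])) {
        if (placed >= n) break
        ci <- off_chk[, 1] + i; cj <- off_chk[, 2] + j; ck <- off_chk[, 3] + k
        ok <- ci >= 1 & ci <= d[1] & cj >= 1 & cj <= d[2] & ck >= 1 & ck <= d[3]
        if (!all(ok)) next
        idx <- cbind(ci, cj, ck)
        if (!all(body[idx])) next
        if (!is.null(exclude) && any(exclude[idx])) next
        if (any(taken[idx])) next
        vi <- cbind(off_voi[, 1] + i, off_voi[, 2] + j, off_voi[, 3] + k)
        out[vi] <- TRUE
        taken[idx] <- TRUE
        centers <- rbind(centers, c(i, j, k))
        placed <- placed + 1L
      }
    }
  }
  if (placed < n)
    stop(sprintf("background_vois: only %d of %d VOIs could be placed", placed, n))
  attr(out, "centers") <- centers
  out
}

#' Per-lesion, per-arm quantification table
#'
#' Builds the standard evaluation table of a phantom experiment: one row per
#' lesion per method arm (plus an `EXP` row holding the declared intended
#' ratio), with LBR_max, LBR_A50, LBR_mean and, when an `uncorrected` arm
#' is named, the relative changes.
#'
#' @param phantom a `phantom` (ground truth; lesion masks come from its
#'   label map, HU from its HU map).
#' @param arms named list of method arms. Each arm is either an
#'   `image_volume` (image-based arm) or a numeric vector of per-lesion
#'   ratios (an LP tissue-activity arm, one value per lesion in label
#'   order; `NA` marks an absent lesion).
#' @param background_mask logical mask for the background activity
#'   measurement (see [background_vois()]).
#' @param uncorrected name of the reference (uncorrected) image arm for the
#'   delta columns, or `NULL`.
#' @param file optional CSV output path.
#' @return A data frame.
#' @export
evaluate_phantom_experiment <- function(phantom, arms, background_mask,
                                        uncorrected = NULL, file = NULL) {
  stopifnot(inherits(phantom, "phantom"), !is.null(phantom$intended))
  les <- phantom$intended
  rows <- list()
  ratio_of <- function(arm, id, what) {
    mask <- phantom$label$values == id
    if (is_image_volume(arm)) {
      bg <- mean(arm$values[background_mask])
      switch(what,
             max = lbr_max(arm, mask, background_mask),
             a50 = lbr_a50(arm, mask, bg),
             mean = lbr_mean(arm, mask, background_mask))
    } else if (what == "max") arm[id] else NA_real_
  }
  ref <- if (!is.null(uncorrected)) arms[[uncorrected]] else NULL
  for (id in les$id) {
    hu_max <- max(phantom$hu$values[phantom$label$values == id])
    for (arm_name in names(arms)) {
      arm <- arms[[arm_name]]
      absent <- !is_image_volume(arm) && (length(arm) < id || is.na(arm[id]))
      lmx <- if (absent) NA_real_ else ratio_of(arm, id, "max")
      la5 <- if (absent) NA_real_ else ratio_of(arm, id, "a50")
      lmn <- if (absent) NA_real_ else ratio_of(arm, id, "mean")
      dmx <- if (!is.null(ref) && !identical(arm_name, uncorrected) &&
                 is.finite(lmx)) delta_lbr(lmx, ratio_of(ref, id, "max")) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        lesion = id, volume_mm3 = les$volume_mm3[les$id == id],
        hu_max = hu_max,
        plaque_class = as.character(classify_plaque(hu_max)),
        arm = arm_name, lbr_max = lmx, lbr_a50 = la5, lbr_mean = lmn,
        delta_lbr_max = dmx)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      lesion = id, volume_mm3 = les$volume_mm3[les$id == id], hu_max = hu_max,
      plaque_class = as.character(classify_plaque(hu_max)),
      arm = "EXP", lbr_max = les$lbr[les$id == id], lbr_a50 = les$lbr[les$id == id],
      lbr_mean = les$lbr[les$id == id], delta_lbr_max = NA_real_)
  }
  out <- do.call(rbind, rows)
  if (!is.null(file)) write.csv(out, file, row.names = FALSE)
  out
}
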