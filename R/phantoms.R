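# Digital phantoms: declarative specs rasterized into companion activity /
# attenuation / HU / label volumes. Lesions are always spheres and are
# rasterized with fractional voxel occupancy so that sub-voxel "plaque-type"
# lesions conserve their activity mass; body compartments are large and are
# rasterized by voxel-centre inclusion.

MU_WATER <- 0.0096   # mm^-1 at 511 keV
MU_BONE  <- 0.017    # mm^-1, bone / dense calcification

#' Declarative phantom specification
#'
#' Describes a phantom as a list of body primitives (elliptical cylinders or
#' ellipsoids, rasterized by voxel-centre inclusion) plus a list of spherical
#' lesions (rasterized with fractional occupancy). Lesions may be given by
#' `diameter_mm` or by `volume_mm3`; the conversion `d = (6 V / pi)^(1/3)` is
#' exact. Each lesion's intended (pre-rasterization) activity is recorded so
#' that the declared lesion-to-background ratio is available as the ground
#' truth even for sub-voxel lesions whose voxelized peak is diluted by
#' partial occupancy.
#'
#' @param grid_shape integer triple, voxels per axis.
#' @param voxel_size_mm voxel size in mm (length 1 or 3). Default 2.03 mm
#'   isotropic, a typical clinical PET reconstruction voxel.
#' @param body list of primitives; each a list with `type` ("cylinder" or
#'   "ellipsoid"), `center` (mm), `semi_axes` (mm; for a cylinder the x/y
#'   semi-axes plus `length` along z), `activity` (kBq/mL), `mu` (mm^-1) and
#'   `hu`.
#' @param lesions list of lesions; each a list with `center` (mm), one of
#'   `diameter_mm` / `volume_mm3`, `activity` (kBq/mL), `hu`, optional `mu`.
#' @param background_activity background activity in kBq/mL (used for the
#'   declared lesion-to-background ratios).
#' @param seed integer, recorded for provenance (phantom construction itself
#'   is deterministic).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(128L, 128L, 48L),
                         voxel_size_mm = 2.03,
                         body = list(),
                         lesions = list(),
                         background_activity = 1,
                         seed = 1L) {
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(voxel_size_mm <= 0)) stop("phantom_spec: voxel sizes must be > 0")
  if (background_activity < 0) stop("phantom_spec: background activity must be >= 0")
  lesions <- lapply(lesions, function(l) {
    if (is.null(l$diameter_mm)) {
      if (is.null(l$volume_mm3)) stop("phantom_spec: lesion needs diameter_mm or volume_mm3")
      if (l$volume_mm3 <= 0) stop("phantom_spec: lesion volume must be > 0")
      l$diameter_mm <- (6 * l$volume_mm3 / pi)^(1 / 3)
    }
    if (l$diameter_mm <= 0) stop("phantom_spec: lesion diameter must be > 0")
    l$volume_mm3 <- pi / 6 * l$diameter_mm^3
    if (is.null(l$hu)) l$hu <- 0
    if (is.null(l$mu)) l$mu <- if (l$hu >= 110) MU_BONE else MU_WATER
    l
  })
  structure(list(grid_shape = as.integer(grid_shape), voxel_size_mm = voxel_size_mm,
                 body = body, lesions = lesions,
                 background_activity = background_activity, seed = as.integer(seed)),
            class = "phantom_spec")
}

grid_descriptor <- function(spec) {
  list(dim = spec$grid_shape, voxel_size_mm = spec$voxel_size_mm,
       origin_mm = -(spec$grid_shape - 1) / 2 * spec$voxel_size_mm)
}

#' Fractional-occupancy rasterization of a sphere
#'
#' Computes, for every voxel, the fraction of its volume inside the sphere.
#' Fully interior/exterior voxels are resolved analytically; boundary voxels
#' are supersampled on an `nsub`^3 sub-grid. The rasterization conserves the
#' sphere volume: `sum(values) * voxel_volume` approximates `pi/6 d^3`.
#'
#' @param center_mm sphere centre (mm).
#' @param diameter_mm sphere diameter (mm, > 0).
#' @param grid list with `dim` (integer triple), `voxel_size_mm`,
#'   `origin_mm` — as returned by the internal grid descriptor of a
#'   [phantom_spec()].
#' @param nsub supersampling factor per axis for boundary voxels.
#' @return An `image_volume` (role `"activity"`) of occupancies in `[0, 1]`.
#' @export
rasterize_sphere <- function(center_mm, diameter_mm, grid, nsub = 16L) {
  if (diameter_mm <= 0) stop("rasterize_sphere: diameter must be > 0")
  occ <- cpp_sphere_occupancy(as.integer(grid$dim), as.numeric(grid$voxel_size_mm),
                              as.numeric(grid$origin_mm), as.numeric(center_mm),
                              diameter_mm, as.integer(nsub))
  if (sum(occ) == 0) stop("rasterize_sphere: empty rasterization (sphere outside grid)")
  image_volume(occ, grid$voxel_size_mm, "activity", grid$origin_mm)
}

inside_primitive <- function(p, X, Y, Z) {
  cen <- p$center
  switch(p$type,
    cylinder = {
      a <- p$semi_axes[1]; b <- if (length(p$semi_axes) > 1) p$semi_axes[2] else a
      ((X - cen[1]) / a)^2 + ((Y - cen[2]) / b)^2 <= 1 &
        abs(Z - cen[3]) <= p$length / 2
    },
    ellipsoid = {
      ((X - cen[1]) / p$semi_axes[1])^2 + ((Y - cen[2]) / p$semi_axes[2])^2 +
        ((Z - cen[3]) / p$semi_axes[3])^2 <= 1
    },
    stop(sprintf("unknown primitive type '%s'", p$type)))
}

#' Rasterize a phantom specification
#'
#' Produces the four companion volumes (activity, attenuation, HU, label)
#' plus the intended per-lesion reference table. Body primitives are painted
#' in order; lesions are composited on top with occupancy weighting
#' (`value <- value * (1 - occ) + lesion_value * occ`), which preserves the
#' lesion's activity mass even when the lesion is smaller than a voxel.
#' Label ids 1..n mark voxels with lesion occupancy >= 0.5.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom`: list with `activity`, `mu`, `hu`,
#'   `label` (`image_volume`s), `body` (logical in-body mask), `intended`
#'   (data frame of declared lesion properties incl. the declared
#'   lesion-to-background ratio), `background_activity`, `gt_lbr`, `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- grid_descriptor(spec)
  d <- g$dim
  xs <- axis_coords(d[1], g$voxel_size_mm[1], g$origin_mm[1])
  ys <- axis_coords(d[2], g$voxel_size_mm[2], g$origin_mm[2])
  zs <- axis_coords(d[3], g$voxel_size_mm[3], g$origin_mm[3])
  X <- array(xs, d); Y <- array(rep(ys, each = d[1]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)

  act <- array(0, d); mu <- array(0, d); hu <- array(-1000, d)
  body_mask <- array(FALSE, d)
  for (p in spec$body) {
    m <- inside_primitive(p, X, Y, Z)
    act[m] <- if (is.null(p$activity)) spec$background_activity else p$activity
    mu[m] <- if (is.null(p$mu)) MU_WATER else p$mu
    hu[m] <- if (is.null(p$hu)) 0 else p$hu
    body_mask <- body_mask | m
  }

  nl <- length(spec$lesions)
  if (nl > 1) {
    for (i in seq_len(nl - 1)) for (j in (i + 1):nl) {
      li <- spec$lesions[[i]]; lj <- spec$lesions[[j]]
      if (sqrt(sum((li$center - lj$center)^2)) <
          (li$diameter_mm + lj$diameter_mm) / 2)
        stop(sprintf("build_phantom: overlapping lesions %d and %d", i, j))
    }
  }

  label <- array(0L, d)
  intended <- NULL
  for (i in seq_len(nl)) {
    l <- spec$lesions[[i]]
    occ <- rasterize_sphere(l$center, l$diameter_mm, g)$values
    act <- act * (1 - occ) + l$activity * occ
    mu <- mu * (1 - occ) + l$mu * occ
    hu <- hu * (1 - occ) + l$hu * occ
    label[occ >= 0.5] <- i
    intended <- rbind(intended, data.frame(
      id = i, cx = l$center[1], cy = l$center[2], cz = l$center[3],
      diameter_mm = l$diameter_mm, volume_mm3 = l$volume_mm3,
      activity_kbq_ml = l$activity, hu = l$hu,
      lbr = if (spec$background_activity > 0) l$activity / spec$background_activity else NA_real_))
  }

  structure(list(
    activity = image_volume(act, g$voxel_size_mm, "activity", g$origin_mm),
    mu = image_volume(mu, g$voxel_size_mm, "mu", g$origin_mm),
    hu = image_volume(hu, g$voxel_size_mm, "hu", g$origin_mm),
    label = image_volume(label, g$voxel_size_mm, "label", g$origin_mm),
    body = body_mask,
    intended = intended,
    background_activity = spec$background_activity,
    gt_lbr = if (is.null(intended)) 1 else max(intended$lbr),
    spec = spec), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  d <- dim(x$activity$values)
  cat(sprintf("<phantom> %d x %d x %d @ %.3g mm, background %.3g kBq/mL, %d lesion(s)\n",
              d[1], d[2], d[3], x$activity$voxel_size_mm[1],
              x$background_activity, if (is.null(x$intended)) 0L else nrow(x$intended)))
  if (!is.null(x$intended)) print(x$intended, digits = 4)
  invisible(x)
}

#' NEMA IQ-like phantom specification
#'
#' Torso-sized elliptical cylinder with six fillable hot spheres (default
#' internal diameters 10, 13, 17, 22, 28 and 37 mm) on a ring in the central
#' transaxial plane, at a configurable sphere-to-background activity ratio.
#'
#' @param ratio sphere-to-background activity ratio (default 4.95).
#' @param background_activity background activity, kBq/mL (default 4.8).
#' @param sphere_diameters_mm sphere internal diameters, mm.
#' @param ring_radius_mm radius of the sphere-centre ring, mm.
#' @param sphere_hu CT density assigned to the spheres (default 300, so a
#'   calcification-style 110-HU threshold segments them).
#' @param grid_shape,voxel_size_mm grid geometry.
#' @param body_semi_axes_mm x/y semi-axes of the body cylinder, mm.
#' @param seed recorded provenance seed.
#' @return A [phantom_spec()].
#' @export
nema_iq_spec <- function(ratio = 4.95, background_activity = 4.8,
                         sphere_diameters_mm = c(10, 13, 17, 22, 28, 37),
                         ring_radius_mm = 57.2, sphere_hu = 300,
                         grid_shape = c(128L, 128L, 48L), voxel_size_mm = 2.03,
                         body_semi_axes_mm = c(118, 88), seed = 1L) {
  if (ratio <= 0) stop("nema_iq_spec: sphere-to-background ratio must be > 0")
  nz_mm <- grid_shape[3] * rep_len(voxel_size_mm, 3L)[3]
  body <- list(list(type = "cylinder", center = c(0, 0, 0),
                    semi_axes = body_semi_axes_mm, length = 0.92 * nz_mm,
                    activity = background_activity, mu = MU_WATER, hu = 0))
  ang <- (seq_along(sphere_diameters_mm) - 1) * 2 * pi / length(sphere_diameters_mm)
  lesions <- mapply(function(d, a) {
    list(center = c(ring_radius_mm * cos(a), ring_radius_mm * sin(a), 0),
         diameter_mm = d, activity = ratio * background_activity, hu = sphere_hu)
  }, sphere_diameters_mm, ang, SIMPLIFY = FALSE)
  phantom_spec(grid_shape, voxel_size_mm, body, lesions, background_activity, seed)
}

#' @rdname nema_iq_spec
#' @param spec a [phantom_spec()] as produced by `nema_iq_spec()`.
#' @export
build_nema_iq <- function(spec = nema_iq_spec()) build_phantom(spec)

#' Thorax phantom specification with plaque-type lesions
#'
#' Human-thorax-sized elliptical cylinder with three small spherical
#' "plaque-type" lesions declared by volume (default 36, 31 and 18 mm^3 —
#' diameters 4.1, 3.9 and 3.2 mm, i.e. below or near the voxel pitch) at a
#' high lesion-to-background ratio (default 70:1). Lesion positions default
#' to three mediastinal locations and are ordinary spec fields.
#'
#' @param lbr lesion-to-background activity ratio (default 70).
#' @param background_activity background activity, kBq/mL (default 4.0).
#' @param lesion_volumes_mm3 lesion volumes, mm^3.
#' @param lesion_centers_mm list of lesion centres, mm.
#' @param lesion_hu CT density of the lesions (default 600).
#' @param grid_shape,voxel_size_mm grid geometry.
#' @param body_semi_axes_mm x/y semi-axes of the body cylinder, mm.
#' @param seed recorded provenance seed.
#' @return A [phantom_spec()].
#' @export
thorax_plaque_spec <- function(lbr = 70, background_activity = 4.0,
                               lesion_volumes_mm3 = c(36, 31, 18),
                               lesion_centers_mm = list(c(0, 25, 0),
                                                        c(-30, -10, 8.12),
                                                        c(30, -10, -8.12)),
                               lesion_hu = 600,
                               grid_shape = c(128L, 128L, 48L), voxel_size_mm = 2.03,
                               body_semi_axes_mm = c(115, 80), seed = 1L) {
  if (lbr <= 0) stop("thorax_plaque_spec: lesion-to-background ratio must be > 0")
  if (any(lesion_volumes_mm3 <= 0)) stop("thorax_plaque_spec: lesion volumes must be > 0")
  nz_mm <- grid_shape[3] * rep_len(voxel_size_mm, 3L)[3]
  body <- list(list(type = "cylinder", center = c(0, 0, 0),
                    semi_axes = body_semi_axes_mm, length = 0.92 * nz_mm,
                    activity = background_activity, mu = MU_WATER, hu = 0))
  lesions <- mapply(function(v, cen) {
    list(center = cen, volume_mm3 = v, activity = lbr * background_activity,
         hu = lesion_hu)
  }, lesion_volumes_mm3, lesion_centers_mm, SIMPLIFY = FALSE)
  phantom_spec(grid_shape, voxel_size_mm, body, lesions, background_activity, seed)
}

#' @rdname thorax_plaque_spec
#' @param spec a [phantom_spec()] as produced by `thorax_plaque_spec()`.
#' @export
build_thorax_plaque <- function(spec = thorax_plaque_spec()) build_phantom(spec)

#' Synthetic carotid-section phantom
#'
#' A neck-sized soft-tissue cylinder containing a vertical vessel of uniform
#' blood-pool activity with a single spherical plaque lesion on the vessel
#' wall. The plaque HU is configurable across the non-calcified to heavily
#' calcified range and its volume across the clinically reported range. A
#' companion `reference_mask` marks an arterial background segment located
#' 10-15 mm below the plaque, for the background activity measurement.
#'
#' @param plaque_volume_mm3 plaque volume (mm^3, > 0, or 0 for a
#'   lesion-free vessel).
#' @param plaque_hu plaque CT density (drives the four-class taxonomy).
#' @param lbr plaque-to-blood activity ratio.
#' @param background_activity arterial blood-pool activity (kBq/mL).
#' @param vessel_radius_mm vessel lumen+wall radius (mm).
#' @param tissue_activity surrounding soft-tissue activity (kBq/mL).
#' @param plaque_z_mm axial position of the plaque centre (mm).
#' @param grid_shape,voxel_size_mm grid geometry.
#' @param seed recorded provenance seed.
#' @return A `phantom` with an extra `reference_mask` element.
#' @export
carotid_section_spec <- function(plaque_volume_mm3 = 50, plaque_hu = 600,
                                 lbr = 3, background_activity = 2.0,
                                 vessel_radius_mm = 5, tissue_activity = 1.0,
                                 plaque_z_mm = 10,
                                 grid_shape = c(64L, 64L, 48L), voxel_size_mm = 2.03,
                                 seed = 1L) {
  nz_mm <- grid_shape[3] * rep_len(voxel_size_mm, 3L)[3]
  body <- list(
    list(type = "cylinder", center = c(0, 0, 0), semi_axes = c(55, 55),
         length = 0.95 * nz_mm, activity = tissue_activity, mu = MU_WATER, hu = 40),
    list(type = "cylinder", center = c(0, 0, 0),
         semi_axes = c(vessel_radius_mm, vessel_radius_mm),
         length = 0.95 * nz_mm, activity = background_activity, mu = MU_WATER, hu = 45))
  lesions <- list()
  if (plaque_volume_mm3 > 0) {
    dia <- (6 * plaque_volume_mm3 / pi)^(1 / 3)
    center <- c(vessel_radius_mm - dia / 4, 0, plaque_z_mm)
    if (sqrt(sum(center[1:2]^2)) > vessel_radius_mm)
      stop("carotid_section_spec: plaque outside vessel")
    lesions <- list(list(center = center, volume_mm3 = plaque_volume_mm3,
                         activity = lbr * background_activity, hu = plaque_hu))
  }
  spec <- phantom_spec(grid_shape, voxel_size_mm, body, lesions,
                       background_activity, seed)
  spec$vessel_radius_mm <- vessel_radius_mm
  spec$plaque_z_mm <- plaque_z_mm
  spec
}

#' @rdname carotid_section_spec
#' @param spec a spec as produced by `carotid_section_spec()`.
#' @export
build_carotid_section <- function(spec = carotid_section_spec()) {
  ph <- build_phantom(spec)
  g <- grid_descriptor(spec)
  d <- g$dim
  xs <- axis_coords(d[1], g$voxel_size_mm[1], g$origin_mm[1])
  ys <- axis_coords(d[2], g$voxel_size_mm[2], g$origin_mm[2])
  zs <- axis_coords(d[3], g$voxel_size_mm[3], g$origin_mm[3])
  X <- array(xs, d); Y <- array(rep(ys, each = d[1]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)
  ph$reference_mask <- (X^2 + Y^2 <= spec$vessel_radius_mm^2) &
    (Z <= spec$plaque_z_mm - 10) & (Z >= spec$plaque_z_mm - 15)
  ph
}
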