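#' 3D image volume with voxel spacing and a semantic role
#'
#' Thin container used throughout the package for voxelized maps: activity
#' concentration (kBq/mL), 511-keV linear attenuation (mm^-1), CT density
#' (Hounsfield units) or integer tissue/lesion labels. The grid is indexed
#' `[x, y, z]` and the default origin centres the grid on (0,0,0) mm, which
#' is also the rotation centre of the projection geometry.
#'
#' @param values 3D numeric array.
#' @param voxel_size_mm voxel edge lengths in mm (length 1 or 3, all > 0).
#' @param role one of `"activity"`, `"mu"`, `"hu"`, `"label"`.
#' @param origin_mm coordinates (mm) of the centre of voxel `[1,1,1]`;
#'   default centres the grid.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, voxel_size_mm, role = c("activity", "mu", "hu", "label"),
                         origin_mm = NULL) {
  role <- match.arg(role)
  if (length(dim(values)) != 3L)
    stop("image_volume: `values` must be a 3D array")
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(voxel_size_mm <= 0)) stop("image_volume: voxel sizes must be > 0")
  if (role %in% c("activity", "mu") && any(values < 0))
    stop(sprintf("image_volume: %s values must be non-negative", role))
  if (role == "label") {
    if (any(values < 0) || any(values != round(values)))
      stop("image_volume: label values must be non-negative integers")
    storage.mode(values) <- "integer"
  }
  if (is.null(origin_mm)) origin_mm <- -(dim(values) - 1) / 2 * voxel_size_mm
  structure(list(values = values, voxel_size_mm = voxel_size_mm,
                 origin_mm = as.numeric(origin_mm), role = role),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<image_volume> role=%s  %d x %d x %d voxels @ %.3g x %.3g x %.3g mm\n",
              x$role, d[1], d[2], d[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  cat(sprintf("  range [%.4g, %.4g], origin (%.4g, %.4g, %.4g) mm\n",
              min(x$values), max(x$values),
              x$origin_mm[1], x$origin_mm[2], x$origin_mm[3]))
  invisible(x)
}

#' @rdname image_volume
#' @param x object to test.
#' @export
is_image_volume <- function(x) inherits(x, "image_volume")

voxel_volume <- function(vol) prod(vol$voxel_size_mm)

stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a$values), dim(b$values)) ||
      max(abs(a$voxel_size_mm - b$voxel_size_mm)) > 1e-9)
    stop(sprintf("grid mismatch between companion %s", what))
  invisible(TRUE)
}

#' Replace the voxel array of a volume, keeping grid metadata
#' @param vol an `image_volume` template.
#' @param values replacement 3D array (same shape).
#' @param role optional new role.
#' @return An `image_volume`.
#' @export
with_values <- function(vol, values, role = vol$role) {
  if (!identical(dim(values), dim(vol$values)))
    stop("with_values: shape mismatch")
  image_volume(values, vol$voxel_size_mm, role, vol$origin_mm)
}

#' Voxel-centre coordinates of a grid axis
#' @noRd
axis_coords <- function(n, vox, orig) orig + (seq_len(n) - 1) * vox

#' Integer-voxel rigid shift of a volume
#'
#' Utility for synthetic misregistration experiments: shifts the voxel array
#' by whole voxels, zero-filling the vacated border. No interpolation is
#' performed.
#'
#' @param vol an `image_volume`.
#' @param shift_vox integer shifts (length 3) in voxels along x, y, z.
#' @return The shifted `image_volume`.
#' @export
shift_volume <- function(vol, shift_vox) {
  shift_vox <- as.integer(rep_len(shift_vox, 3L))
  d <- dim(vol$values)
  out <- array(0, d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    s <- shift_vox[ax]
    if (abs(s) >= d[ax]) return(with_values(vol, out))
    if (s >= 0) { src[[ax]] <- 1:(d[ax] - s); dst[[ax]] <- (1 + s):d[ax] }
    else        { src[[ax]] <- (1 - s):d[ax]; dst[[ax]] <- 1:(d[ax] + s) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- vol$values[src[[1]], src[[2]], src[[3]]]
  with_values(vol, out)
}
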