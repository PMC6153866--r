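# File formats: volumes as NIfTI-1 with a JSON sidecar carrying the
# semantic role and origin; sinograms as an RDS array with a JSON sidecar
# carrying the geometry (angles, radial bin, counts flag, seed); phantom
# specifications as YAML.

sidecar_path <- function(path) paste0(sub("\\.nii(\\.gz)?$|\\.rds$", "", path), ".json")

#' Write / read an image volume (NIfTI-1 + JSON sidecar)
#'
#' The voxel size is stored in the NIfTI header; the semantic role and the
#' origin are stored in a JSON sidecar next to the image.
#'
#' @param vol an `image_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `write_volume`: the path, invisibly. `read_volume`: an
#'   `image_volume`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_image_volume(vol))
  img <- RNifti::asNifti(vol$values * 1)
  RNifti::pixdim(img) <- vol$voxel_size_mm
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(role = vol$role, origin_mm = vol$origin_mm),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @param role role override when no sidecar is present.
#' @export
read_volume <- function(path, role = NULL) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("read_volume: expected a 3D volume")
  vals <- array(as.numeric(img), dim(img))
  vox <- RNifti::pixdim(img)[1:3]
  side <- sidecar_path(path)
  origin <- NULL
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (is.null(role)) role <- meta$role
    origin <- meta$origin_mm
  }
  if (is.null(role)) role <- "activity"
  if (role == "label") vals <- array(as.integer(round(vals)), dim(vals))
  image_volume(vals, vox, role, origin)
}

#' Write / read a sinogram (RDS array + JSON sidecar)
#'
#' @param sino a `sinogram`.
#' @param path output path (`.rds`).
#' @return `write_sinogram`: the path, invisibly. `read_sinogram`: a
#'   `sinogram`.
#' @export
write_sinogram <- function(sino, path) {
  stopifnot(inherits(sino, "sinogram"))
  saveRDS(sino$values, path)
  jsonlite::write_json(list(dims = dim(sino$values), angles = sino$angles,
                            radial_bin_mm = sino$radial_bin_mm,
                            counts_flag = sino$counts_flag, seed = sino$seed),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  vals <- readRDS(path)
  side <- sidecar_path(path)
  if (!file.exists(side)) stop("read_sinogram: missing JSON sidecar")
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (!identical(as.integer(meta$dims), as.integer(dim(vals))))
    stop("read_sinogram: sidecar / array geometry mismatch")
  sinogram(vals, meta$angles, meta$radial_bin_mm, isTRUE(meta$counts_flag),
           meta$seed)
}

#' Write / read a phantom specification (YAML)
#'
#' @param spec a [phantom_spec()].
#' @param path output path (`.yaml`).
#' @return `write_phantom_spec`: the path, invisibly. `read_phantom_spec`:
#'   a `phantom_spec`.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  numify <- function(p) lapply(p, function(f) if (is.list(f)) unlist(f) else f)
  phantom_spec(grid_shape = unlist(raw$grid_shape),
               voxel_size_mm = unlist(raw$voxel_size_mm),
               body = lapply(raw$body, numify),
               lesions = lapply(raw$lesions, numify),
               background_activity = raw$background_activity,
               seed = if (is.null(raw$seed)) 1L else raw$seed)
}

#' Bundled phantom/simulation settings for small-scale runs
#'
#' Returns ready-made phantom specifications and matching simulation
#' settings at two problem sizes: `"tiny"` (64 x 64 x 16 grid, 60 views;
#' builds in seconds, used by the test suite) and `"desk"` (the default
#' 128 x 128 x 48 grid, 120 views). Optionally writes the specs as YAML to
#' a directory.
#'
#' @param scale `"tiny"` or `"desk"`.
#' @param dir optional directory to write the YAML specs into.
#' @return List with `nema`, `thorax`, `carotid` ([phantom_spec()]s) and
#'   `sim` (list of simulation settings: `n_angles`, `psf_fwhm_mm`,
#'   `scatter_fraction`, `total_counts`).
#' @export
fixture_generator <- function(scale = c("tiny", "desk"), dir = NULL) {
  scale <- match.arg(scale)
  if (scale == "tiny") {
    grid <- c(64L, 64L, 16L)
    out <- list(
      nema = nema_iq_spec(grid_shape = grid, body_semi_axes_mm = c(62, 55),
                          ring_radius_mm = 32,
                          sphere_diameters_mm = c(10, 13, 17, 22)),
      thorax = thorax_plaque_spec(grid_shape = grid,
                                  body_semi_axes_mm = c(62, 55),
                                  lesion_centers_mm = list(c(0, 20, 0),
                                                           c(-22, -10, 4.06),
                                                           c(22, -10, -4.06))),
      carotid = carotid_section_spec(grid_shape = c(64L, 64L, 24L)),
      sim = list(n_angles = 60L, psf_fwhm_mm = 4, scatter_fraction = 0.2,
                 total_counts = 2e5))
  } else {
    out <- list(nema = nema_iq_spec(), thorax = thorax_plaque_spec(),
                carotid = carotid_section_spec(),
                sim = list(n_angles = 120L, psf_fwhm_mm = 4,
                           scatter_fraction = 0.2, total_counts = 1e6))
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("nema", "thorax", "carotid"))
      write_phantom_spec(out[[nm]], file.path(dir, paste0(nm, ".yaml")))
    jsonlite::write_json(out$sim, file.path(dir, "sim.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
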