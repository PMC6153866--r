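# Shared fixtures, memoised so expensive simulations are built once per
# test run. All fixtures are generated in code; nothing is read from disk.

.fx <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fx[[name]])) assign(name, build(), envir = .fx)
  get(name, envir = .fx)
}

tiny_grid <- function(dim = c(32L, 32L, 12L), vox = 2.03) {
  list(dim = as.integer(dim), voxel_size_mm = rep(vox, 3),
       origin_mm = -(dim - 1) / 2 * vox)
}

# single 13-mm hot sphere (ratio 4.95, background 4.8) in a small body
tiny_sphere_spec <- function(diameter = 13) {
  nema_iq_spec(grid_shape = c(48L, 48L, 24L), body_semi_axes_mm = c(42, 38),
               ring_radius_mm = 0, sphere_diameters_mm = diameter)
}

tiny_phantom <- function() fx("tiny_phantom", function() build_phantom(tiny_sphere_spec()))

# noise-free acquisition of the tiny phantom (4-mm PSF, 20% scatter)
tiny_sim <- function() fx("tiny_sim", function()
  simulate_acquisition(tiny_phantom(), psf_fwhm_mm = 4, scatter_fraction = 0.2,
                       total_counts = 4e5, n_angles = 48L, seed = 1L,
                       noise = FALSE))

tiny_recon <- function() fx("tiny_recon", function()
  osem(tiny_sim()$counts, tiny_sim()$model, recon_config(5L, 12L)))

# attenuation-free system model on an arbitrary grid
flat_model <- function(dim, vox = 2.03, n_angles = 32L, psf_fwhm_mm = 4,
                       count_scale = 1) {
  mu <- image_volume(array(0, dim), vox, "mu")
  geom <- projection_geometry(dim, vox, n_angles)
  system_model(psf_fwhm_mm, compute_attenuation_factors(mu, geom),
               count_scale = count_scale, img_dim = as.integer(dim),
               voxel_size_mm = vox)
}

# independent sphere-occupancy oracle: plain-R midpoint supersampling at 8^3
oracle_occupancy <- function(center, diameter, grid, nsub = 8L) {
  d <- grid$dim; vox <- grid$voxel_size_mm; org <- grid$origin_mm
  occ <- array(0, d)
  R2 <- (diameter / 2)^2
  sub <- (seq_len(nsub) - 0.5) / nsub - 0.5
  offs <- as.matrix(expand.grid(sub * vox[1], sub * vox[2], sub * vox[3]))
  lo <- pmax(1, floor((center - diameter / 2 - org) / vox) + 1 - 1)
  hi <- pmin(d, ceiling((center + diameter / 2 - org) / vox) + 1 + 1)
  for (k in lo[3]:hi[3]) for (j in lo[2]:hi[2]) for (i in lo[1]:hi[1]) {
    cen <- org + (c(i, j, k) - 1) * vox - center
    pts <- sweep(offs, 2, -cen)
    occ[i, j, k] <- mean(rowSums(pts^2) <= R2)
  }
  occ
}

# image-profile FWHM along x through the global maximum, by linear
# interpolation of the half-maximum crossings
profile_fwhm <- function(img_values, vox) {
  idx <- which(img_values == max(img_values), arr.ind = TRUE)[1, ]
  pr <- img_values[, idx[2], idx[3]]
  half <- max(pr) / 2
  above <- which(pr >= half)
  a <- min(above); b <- max(above)
  left <- if (a > 1) a - (pr[a] - half) / (pr[a] - pr[a - 1]) else a
  right <- if (b < length(pr)) b + (pr[b] - half) / (pr[b] - pr[b + 1]) else b
  (right - left) * vox
}
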