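test_that("attenuation factors follow the exponential line-integral law", {
  d <- c(128L, 128L, 4L)
  vox <- 2.03
  xs <- (seq_len(d[1]) - (d[1] + 1) / 2) * vox
  X <- array(xs, d); Y <- array(rep(xs, each = d[1]), d)
  muv <- array(0, d)
  muv[X^2 + Y^2 <= 100^2] <- 0.0096      # water cylinder, diameter 200 mm
  mu <- image_volume(muv, vox, "mu")
  geom <- projection_geometry(d, vox, n_angles = 8L)
  att <- compute_attenuation_factors(mu, geom)
  expect_true(all(att$values > 0 & att$values <= 1))
  # central bin crosses the full 200-mm diameter: factor exp(-0.0096*200)
  expect_equal(att$values[1, d[1] / 2, 2], exp(-1.92), tolerance = 0.02)
  # doubling mu squares every factor (exact property of the exponential)
  att2 <- compute_attenuation_factors(with_values(mu, 2 * muv), geom)
  expect_equal(att2$values, att$values^2, tolerance = 1e-12)
  # zero attenuation is the identity
  att0 <- compute_attenuation_factors(with_values(mu, muv * 0), geom)
  expect_true(all(att0$values == 1))
  expect_error(compute_attenuation_factors(
    image_volume(array(1, d), vox, "hu"), geom), "mu")
})

test_that("projector and back-projector are an exact adjoint pair", {
  set.seed(7)
  d <- c(20L, 20L, 6L)
  mu <- image_volume(array(0.004 * runif(prod(d)), d), 2, "mu")
  geom <- projection_geometry(d, 2, n_angles = 18L)
  m <- system_model(4, compute_attenuation_factors(mu, geom),
                    count_scale = 3.7, img_dim = d, voxel_size_mm = 2)
  x <- image_volume(array(runif(prod(d)), d), 2)
  y <- sinogram(array(runif(18 * 20 * 6), c(18, 20, 6)), m$angles, 2)
  lhs <- sum(forward_project(x, m, include_scatter = FALSE)$values * y$values)
  rhs <- sum(x$values * back_project(y, m)$values)
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
  # and per-subset, as used inside OSEM
  S <- c(2L, 7L, 12L)
  yS <- sinogram(y$values[S, , , drop = FALSE], m$angles[S], 2)
  lhs <- sum(forward_project(x, m, S, include_scatter = FALSE)$values * yS$values)
  rhs <- sum(x$values * back_project(yS, m, S)$values)
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
})

test_that("forward projection is linear and mass-preserving", {
  d <- c(24L, 24L, 8L)
  m <- flat_model(d, n_angles = 24L, count_scale = 5)
  set.seed(3)
  a <- image_volume(array(runif(prod(d)), d), 2.03)
  b <- image_volume(array(runif(prod(d)), d), 2.03)
  pa <- forward_project(a, m, include_scatter = FALSE)$values
  pb <- forward_project(b, m, include_scatter = FALSE)$values
  pab <- forward_project(with_values(a, 2 * a$values + 3 * b$values), m,
                         include_scatter = FALSE)$values
  expect_equal(pab, 2 * pa + 3 * pb, tolerance = 1e-10)
  # single interior voxel: total expected counts = count_scale x voxel volume
  pt <- array(0, d); pt[12, 13, 4] <- 1
  tot <- sum(forward_project(image_volume(pt, 2.03), m,
                             include_scatter = FALSE)$values)
  expect_equal(tot, 5 * 2.03^3, tolerance = 0.005)
  # zero activity projects to zero
  expect_equal(sum(forward_project(with_values(a, a$values * 0), m,
                                   include_scatter = FALSE)$values), 0)
  expect_error(forward_project(image_volume(array(1, c(8, 8, 8)), 2.03), m),
               "mismatch")
})

test_that("a point source projects to a profile with the PSF's width", {
  d <- c(64L, 64L, 8L)
  m <- flat_model(d, n_angles = 4L, psf_fwhm_mm = 4)
  pt <- array(0, d); pt[33, 33, 4] <- 1
  pr <- forward_project(image_volume(pt, 2.03), m, include_scatter = FALSE)$values
  prof <- pr[1, , 4]
  half <- max(prof) / 2
  above <- which(prof >= half)
  a <- min(above); b <- max(above)
  left <- a - (prof[a] - half) / (prof[a] - prof[a - 1])
  right <- b + (prof[b] - half) / (prof[b] - prof[b + 1])
  expect_equal((right - left) * 2.03, 4, tolerance = 2.03 / 2 / 4)
})

test_that("scatter surrogate has the declared total and is smoother than trues", {
  sim <- tiny_sim()
  trues <- forward_project(tiny_phantom()$activity, sim$model,
                           include_scatter = FALSE)
  sc <- estimate_scatter(tiny_phantom()$activity, sim$model, 0.2)
  expect_true(all(sc$values >= 0))
  expect_equal(sum(sc$values), 0.25 * sum(trues$values), tolerance = 1e-3)
  # radial roughness (mean squared second difference) drops under scattering
  rough <- function(v) mean(diff(t(v[1, , ]), differences = 2)^2) / mean(v)^2
  expect_lt(rough(sc$values), 0.2 * rough(trues$values))
  # SF = 0 gives a zero sinogram; SF >= 1 is rejected
  expect_equal(sum(estimate_scatter(tiny_phantom()$activity, sim$model, 0)$values), 0)
  expect_error(estimate_scatter(tiny_phantom()$activity, sim$model, 1), "fraction")
})

test_that("Poisson noise has the right mean, variance and reproducibility", {
  lam <- sinogram(array(50, c(10, 10, 10)), (0:9) * pi / 10, 2)
  c1 <- add_poisson_noise(lam, 11L)
  c2 <- add_poisson_noise(lam, 11L)
  c3 <- add_poisson_noise(lam, 12L)
  expect_identical(c1$values, c2$values)
  expect_false(identical(c1$values, c3$values))
  expect_true(c1$counts_flag)
  expect_true(all(c1$values == round(c1$values)))
  expect_equal(mean(c1$values), 50, tolerance = 3 * sqrt(50 / 1000) / 50)
  lam2 <- sinogram(array(100, c(25, 20, 20)), (0:24) * pi / 25, 2)
  cc <- add_poisson_noise(lam2, 4L)
  expect_equal(var(as.numeric(cc$values)) / mean(cc$values), 1, tolerance = 0.1)
  # zero expectations give zero counts; negative expectations are rejected
  expect_equal(sum(add_poisson_noise(sinogram(array(0, c(4, 4, 2)),
                                              (0:3) * pi / 4, 2), 1L)$values), 0)
  bad <- sinogram(array(1, c(4, 4, 2)), (0:3) * pi / 4, 2)
  bad$values[1] <- -1
  expect_error(add_poisson_noise(bad, 1L), "negative")
})

test_that("simulated acquisitions hit the requested count total", {
  sim <- tiny_sim()
  expect_equal(sum(sim$expectations$values), 4e5, tolerance = 1e-10)
  expect_true(all(sim$model$attenuation$values <= 1))
  expect_equal(sum(sim$model$scatter$values) /
                 (sum(sim$expectations$values) - sum(sim$model$scatter$values)),
               0.25, tolerance = 1e-6)
})
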