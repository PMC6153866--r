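test_that("sphere rasterization conserves volume across the lesion size range", {
  g <- tiny_grid(c(40L, 40L, 24L))
  vvol <- prod(g$voxel_size_mm)
  # sphere of exactly one voxel volume centred on a voxel centre
  d1 <- (6 * vvol / pi)^(1 / 3)
  occ1 <- rasterize_sphere(c(0, 0, 0) + g$voxel_size_mm / 2, d1, g)
  expect_equal(sum(occ1$values), 1, tolerance = 0.02)
  # large and sub-voxel spheres against the analytic volume
  for (dia in c(37, 17, 4.09, 3.25)) {
    occ <- rasterize_sphere(c(1.1, -0.7, 0.4), dia, g)
    expect_equal(sum(occ$values) * vvol, pi / 6 * dia^3, tolerance = 0.02)
    expect_true(all(occ$values >= 0 & occ$values <= 1))
  }
})

test_that("rasterization agrees with an independent supersampled oracle", {
  g <- tiny_grid(c(24L, 24L, 16L))
  for (dia in c(13, 4.09)) {
    occ <- rasterize_sphere(c(0.9, 0.2, -0.5), dia, g)
    orc <- oracle_occupancy(c(0.9, 0.2, -0.5), dia, g)
    expect_equal(sum(occ$values), sum(orc), tolerance = 0.01)
    expect_lt(max(abs(occ$values - orc)), 0.05)
  }
})

test_that("sphere outside the grid and non-positive diameters error", {
  g <- tiny_grid()
  expect_error(rasterize_sphere(c(500, 0, 0), 10, g), "empty rasterization")
  expect_error(rasterize_sphere(c(0, 0, 0), -3, g), "diameter")
})

test_that("NEMA IQ phantom reproduces the declared activities and ratio", {
  ph <- fx("nema_small", function()
    build_phantom(nema_iq_spec(grid_shape = c(96L, 96L, 32L),
                               ring_radius_mm = 40, body_semi_axes_mm = c(90, 70),
                               sphere_diameters_mm = c(10, 13, 17, 22))))
  expect_equal(max(ph$activity$values), 4.95 * 4.8)      # 23.76 kBq/mL
  expect_equal(ph$gt_lbr, 4.95)
  expect_equal(sort(unique(ph$label$values[ph$label$values > 0])), 1:4)
  # ground-truth LBR from the voxel map itself (full-occupancy voxels exist,
  # and the background compartment is untouched away from the spheres)
  bgv <- ph$activity$values[ph$body & ph$label$values == 0]
  expect_gt(mean(bgv == 4.8), 0.98)
  expect_equal(max(ph$activity$values) / 4.8, 4.95, tolerance = 1e-9)
  # equal sphere and background activity gives a flat ratio
  ph1 <- build_phantom(nema_iq_spec(grid_shape = c(48L, 48L, 16L), ratio = 1,
                                    ring_radius_mm = 0,
                                    sphere_diameters_mm = 13,
                                    body_semi_axes_mm = c(42, 38)))
  expect_equal(ph1$gt_lbr, 1)
  expect_equal(max(ph1$activity$values), ph1$background_activity)
})

test_that("phantom construction is deterministic and rejects bad specs", {
  a <- build_phantom(tiny_sphere_spec())
  b <- build_phantom(tiny_sphere_spec())
  expect_identical(a$activity$values, b$activity$values)
  expect_error(nema_iq_spec(ratio = 0), "ratio")
  expect_error(build_phantom(
    nema_iq_spec(grid_shape = c(48L, 48L, 16L), ring_radius_mm = 5,
                 sphere_diameters_mm = c(17, 17))), "overlapping")
})

test_that("thorax phantom converts lesion volumes to diameters exactly", {
  spec <- thorax_plaque_spec()
  dias <- vapply(spec$lesions, `[[`, numeric(1), "diameter_mm")
  expect_equal(dias, (6 * c(36, 31, 18) / pi)^(1 / 3), tolerance = 1e-12)
  expect_equal(round(dias, 2), c(4.09, 3.90, 3.25), tolerance = 0.01)
  expect_error(thorax_plaque_spec(lesion_volumes_mm3 = c(36, -1, 18)), "volume")
  expect_error(thorax_plaque_spec(lbr = 0), "ratio")
})

test_that("thorax phantom preserves intended activities for sub-voxel lesions", {
  ph <- fx("thorax_small", function()
    build_phantom(thorax_plaque_spec(grid_shape = c(64L, 64L, 24L),
                                     body_semi_axes_mm = c(58, 50),
                                     lesion_centers_mm = list(c(0, 20, 0),
                                                              c(-20, -10, 4),
                                                              c(20, -10, -4)))))
  expect_equal(ph$intended$lbr, rep(70, 3))
  expect_equal(ph$intended$activity_kbq_ml, rep(280, 3))
  # voxelized peak is diluted by occupancy but mass is conserved
  expect_lt(max(ph$activity$values), 280)
  vvol <- prod(ph$activity$voxel_size_mm)
  excess <- sum(ph$activity$values - ph$background_activity * ph$body) * vvol
  expect_equal(excess, sum((280 - 4) * c(36, 31, 18)), tolerance = 0.02)
  # unit ratio gives a uniform activity map inside the body
  ph1 <- build_phantom(thorax_plaque_spec(grid_shape = c(48L, 48L, 16L),
                                          body_semi_axes_mm = c(42, 38),
                                          lbr = 1,
                                          lesion_centers_mm = list(c(0, 10, 0),
                                                                   c(-14, -8, 2),
                                                                   c(14, -8, -2))))
  expect_equal(diff(range(ph1$activity$values[ph1$body])), 0, tolerance = 1e-12)
})

test_that("carotid phantom supports the HU taxonomy and reference segment", {
  # a plaque large enough for fully-occupied voxels carries its nominal HU
  ph <- build_carotid_section(carotid_section_spec(plaque_hu = 600,
                                                   plaque_volume_mm3 = 200,
                                                   grid_shape = c(48L, 48L, 32L)))
  hu_max <- max(ph$hu$values[ph$label$values == 1])
  expect_equal(as.character(classify_plaque(hu_max)), "heavy")
  ph2 <- build_carotid_section(carotid_section_spec(plaque_hu = 90,
                                                    grid_shape = c(48L, 48L, 32L)))
  expect_equal(as.character(classify_plaque(max(ph2$hu$values[ph2$label$values == 1]))),
               "non_calcified")
  # reference segment sits 10-15 mm below the plaque, inside the vessel
  zs <- ph$activity$origin_mm[3] +
    (which(apply(ph$reference_mask, 3, any)) - 1) * ph$activity$voxel_size_mm[3]
  expect_true(all(zs <= ph$spec$plaque_z_mm - 10 + 1e-9))
  expect_true(all(zs >= ph$spec$plaque_z_mm - 15 - 1e-9))
  # lesion-free spec: flat unit ratio in the vessel
  ph0 <- build_carotid_section(carotid_section_spec(plaque_volume_mm3 = 0,
                                                    grid_shape = c(48L, 48L, 32L)))
  expect_equal(max(ph0$activity$values) / ph0$background_activity, 1)
  expect_error(carotid_section_spec(plaque_volume_mm3 = 5000, vessel_radius_mm = 2),
               "outside vessel")
})
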