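test_that("CT threshold segmentation selects the calcified component", {
  d <- c(24L, 24L, 8L)
  huv <- array(50, d)
  huv[10:12, 10:12, 3:5] <- 600               # 27-voxel plaque
  huv[20, 20, 4:6] <- 600                     # 3-voxel distractor
  hu <- image_volume(huv, 2.03, "hu")
  m <- segment_ct_threshold(hu, threshold_hu = 110)
  expect_equal(sum(m), 27)
  expect_true(all(which(m) %in% which(huv == 600)))
  expect_error(segment_ct_threshold(with_values(hu, array(50, d), "hu")),
               "no calcified")
})

test_that("PET half-max segmentation thresholds halfway to background", {
  d <- c(24L, 24L, 8L)
  v <- array(4.8, d)
  v[12, 12, 4] <- 23.8
  v[11, 12, 4] <- 15.0    # above (23.8+4.8)/2 = 14.3, connected
  v[14, 12, 4] <- 15.0    # above threshold but NOT face-connected to the max
  pet <- image_volume(v, 2.03)
  m <- segment_pet_halfmax(pet, background_mean = 4.8)
  expect_true(m[12, 12, 4] && m[11, 12, 4])
  expect_false(m[14, 12, 4])
  expect_equal(sum(m), 2)
  # zero background: threshold drops to half the maximum, but only the
  # component connected to the max voxel is kept
  m0 <- segment_pet_halfmax(pet, background_mean = 0)
  expect_true(all(v[m0] >= 23.8 / 2))
  expect_equal(sum(m0), 2)
  expect_error(segment_pet_halfmax(with_values(pet, array(1, d)),
                                   background_mean = 4.8), "not distinguishable")
})

test_that("local VOI partitions its tissues and respects the grid boundary", {
  ph <- tiny_phantom()
  mask <- ph$label$values == 1
  vox <- ph$activity$voxel_size_mm
  voi <- define_local_voi(mask, vox, margin_mm = 12)
  expect_equal(voi$J, 2)
  expect_equal(voi$tissue_names, c("lesion", "background"))
  expect_true(all(voi$labels[voi$mask] > 0))
  expect_true(all(voi$labels[!voi$mask] == 0))
  expect_identical(voi$labels == 1, mask)                  # lesion preserved
  expect_gt(sum(voi$labels == 2), 0)                       # shell non-empty
  # margin 0: lesion only
  expect_equal(define_local_voi(mask, vox, 0)$J, 1)
  # an extra tissue gets its own disjoint label
  extra <- array(FALSE, dim(mask))
  extra[30:32, 22:24, 12] <- TRUE
  voi3 <- define_local_voi(mask, vox, 12, extra_tissues = list(calc = extra))
  expect_equal(voi3$J, 3)
  expect_equal(voi3$tissue_names, c("lesion", "calc", "background"))
  tab <- table(voi3$labels[voi3$mask])
  expect_equal(sum(tab), sum(voi3$mask))                   # exact partition
  # VOI running into the grid edge is refused
  edge_mask <- array(FALSE, dim(mask)); edge_mask[3, 24, 12] <- TRUE
  expect_error(define_local_voi(edge_mask, vox, 12), "boundary")
  # body restriction drops out-of-body shell voxels but keeps the lesion
  body <- ph$mu$values > 0.001
  voir <- define_local_voi(mask, vox, 12, restrict = body)
  expect_true(all(body[voir$mask & voir$labels == 2]))
  expect_identical(voir$labels == 1, mask)
})

test_that("tissue projections sum to the VOI projection and conserve counts", {
  sim <- tiny_sim()
  voi <- define_local_voi(tiny_phantom()$label$values == 1,
                          sim$model$voxel_size_mm, 10)
  tps <- compute_tissue_projections(voi, sim$model)
  whole <- forward_project(image_volume(voi$mask * 1, 2.03), sim$model,
                           include_scatter = FALSE)$values
  expect_lt(max(abs(Reduce(`+`, tps$P) - whole)), 1e-8 * max(whole))
  expect_true(all(tps$support[whole > 1e-6 * max(whole)]))
  # single-voxel tissue, attenuation-free: total = count_scale x voxel volume
  d <- c(24L, 24L, 8L)
  m <- flat_model(d, n_angles = 24L, count_scale = 3)
  one <- array(FALSE, d); one[12, 12, 4] <- TRUE
  voi1 <- define_local_voi(one, 2.03, 0)
  tps1 <- compute_tissue_projections(voi1, m)
  expect_equal(sum(tps1$P[[1]]), 3 * 2.03^3, tolerance = 0.005)
})

test_that("outside-background projection is consistent and non-negative", {
  sim <- tiny_sim()
  ph <- tiny_phantom()
  voi <- define_local_voi(ph$label$values == 1, 2.03, 10)
  g <- estimate_outside_background(ph$activity, voi, sim$model)
  expect_true(all(g$values >= 0))
  # zero image and zero scatter give zero g_out
  m0 <- system_model(4, sim$model$attenuation, count_scale = sim$model$count_scale,
                     img_dim = dim(ph$activity$values), voxel_size_mm = 2.03)
  g0 <- estimate_outside_background(with_values(ph$activity,
                                                ph$activity$values * 0),
                                    voi, m0)
  expect_equal(sum(g0$values), 0)
})

test_that("LP fit recovers exact activities from noise-free matched data", {
  sim <- tiny_sim()
  ph <- tiny_phantom()
  vox <- 2.03
  body <- ph$mu$values > 0.001
  lesion <- ph$label$values == 1
  # piecewise-constant activity on the tissue partition (J = 1, 2, 3)
  for (J in 1:3) {
    extra <- NULL
    if (J == 3) {
      e <- array(FALSE, dim(lesion)); e[28:30, 24:26, 11:13] <- TRUE
      extra <- list(rim = e & !lesion)
    }
    voi <- define_local_voi(lesion, vox, if (J == 1) 0 else 10,
                            extra_tissues = extra, restrict = body)
    truth <- c(23.76, 9.5, 6.2)[seq_len(voi$J)]
    act <- array(4.8, dim(lesion)) * body
    for (j in seq_len(voi$J)) act[voi$labels == j] <- truth[j]
    counts <- forward_project(image_volume(act, vox), sim$model)
    tps <- compute_tissue_projections(voi, sim$model)
    outside <- act; outside[voi$mask] <- 0
    g <- forward_project(image_volume(outside, vox), sim$model)
    fit <- fit_lp_activities(counts, tps, g)
    expect_equal(unname(fit$activities), truth, tolerance = 1e-6)
    expect_true(all(abs(fit$model_counts$values[tps$support] -
                          counts$values[tps$support]) < 1e-6 * max(counts$values)))
  }
})

test_that("scalar LP fit matches its closed form and flags degeneracy", {
  sim <- tiny_sim()
  ph <- tiny_phantom()
  voi <- define_local_voi(ph$label$values == 1, 2.03, 0)
  tps <- compute_tissue_projections(voi, sim$model)
  g <- estimate_outside_background(ph$activity, voi, sim$model)
  fit <- fit_lp_activities(sim$counts, tps, g)
  # brute-force scalar oracle replicating the model-weighted scheme
  sup <- tps$support
  P <- tps$P[[1]][sup]; y <- sim$counts$values[sup]; gg <- g$values[sup]
  A0 <- sum((y - gg) * P) / sum(P^2)
  w <- 1 / pmax(gg + P * A0, 1)
  A1 <- sum(w * (y - gg) * P) / sum(w * P^2)
  expect_equal(unname(fit$activities["lesion"]), A1, tolerance = 1e-9)
  # duplicated shape functions are refused
  tps2 <- tps
  tps2$P <- list(tps$P[[1]], tps$P[[1]] * (1 + 1e-6))
  tps2$tissue_names <- c("lesion", "background")
  expect_error(fit_lp_activities(sim$counts, tps2, g), "degenerate")
})

test_that("a VOI holding no activity fits activities near zero", {
  ph <- tiny_phantom()
  sim <- tiny_sim()
  d <- dim(ph$activity$values)
  # air pocket strictly inside the grid, outside the body
  pocket <- array(FALSE, d)
  pocket[42:44, 42:44, 10:14] <- TRUE
  pocket <- pocket & !(ph$mu$values > 0)
  voi <- define_local_voi(pocket, 2.03, 0)
  tps <- compute_tissue_projections(voi, sim$model)
  g <- estimate_outside_background(ph$activity, voi, sim$model)
  fit <- fit_lp_activities(sim$counts, tps, g)
  expect_lt(abs(fit$activities["lesion"]), 0.1 * ph$background_activity)
})

test_that("substitution is piecewise constant inside and bit-identical outside", {
  ph <- tiny_phantom()
  voi <- define_local_voi(ph$label$values == 1, 2.03, 10)
  img <- tiny_recon()
  fit_vals <- c(lesion = 20, background = 5)
  out <- substitute_voi(img, voi, fit_vals)
  expect_identical(out$values[!voi$mask], img$values[!voi$mask])
  expect_setequal(unique(out$values[voi$mask]), c(20, 5))
  uni <- substitute_voi(img, define_local_voi(ph$label$values == 1, 2.03, 0),
                        c(lesion = 5))
  expect_true(all(uni$values[ph$label$values == 1] == 5))
})

test_that("the full PVC chain improves the lesion and leaves the outside alone", {
  ph <- tiny_phantom()
  sim <- tiny_sim()
  # the clinical uncorrected arm carries the 5-mm protocol postfilter; the
  # corrected reconstruction does not get filtered again
  img <- gaussian_postfilter(tiny_recon(), 5)
  body <- ph$mu$values > 0.001
  res <- run_lp_pvc(sim$counts, img, sim$model,
                    segmentation = list(mode = "ct", hu = ph$hu),
                    margin_mm = 10, restrict = body,
                    recon_cfg = recon_config(5L, 12L), noise = FALSE)
  expect_s3_class(res, "pvc_result")
  expect_identical(res$substituted_image$values[!res$voi$mask],
                   img$values[!res$voi$mask])
  expect_true(all(res$pvc_image$values >= 0))
  bgm <- background_vois(ph$body, 2.03, exclude = ph$label$values > 0,
                         n = 2, diameter_mm = 12)
  lesion <- ph$label$values == 1
  expect_gt(lbr_max(res$pvc_image, lesion, bgm), lbr_max(img, lesion, bgm))
  # stage tagging on failure
  expect_error(run_lp_pvc(sim$counts, img, sim$model,
                          segmentation = list(mode = "ct",
                                              hu = with_values(ph$hu, ph$hu$values * 0 - 1000, "hu"))),
               "\\[segment\\]")
})

test_that("a lesion-free region yields no false enhancement", {
  ph <- fx("flat_phantom", function()
    build_phantom(nema_iq_spec(grid_shape = c(48L, 48L, 24L), ratio = 1,
                               ring_radius_mm = 0, sphere_diameters_mm = 13,
                               body_semi_axes_mm = c(42, 38))))
  sim <- simulate_acquisition(ph, 4, 0.2, 4e5, n_angles = 48L, seed = 1L,
                              noise = FALSE)
  img <- osem(sim$counts, sim$model, recon_config(5L, 12L))
  mask <- ph$label$values == 1          # geometrically defined, activity flat
  res <- run_lp_pvc(sim$counts, img, sim$model, segmentation = mask,
                    margin_mm = 10, restrict = ph$mu$values > 0.001,
                    noise = FALSE, recon_cfg = recon_config(5L, 12L))
  expect_equal(lp_ratio(res$lp_fit), 1, tolerance = 0.05)
})

test_that("FWHM calibration recovers the acquisition blur within half a millimetre", {
  spec <- nema_iq_spec(grid_shape = c(64L, 64L, 24L), body_semi_axes_mm = c(58, 50),
                       ring_radius_mm = 0, sphere_diameters_mm = 32)
  ph <- build_phantom(spec)
  body <- ph$mu$values > 0.001
  for (fw in c(4, 8)) {
    sim <- simulate_acquisition(ph, fw, 0.2, 5e5, seed = 1L, noise = FALSE,
                                n_angles = 60L)
    cal <- calibrate_fwhm(sim$counts, model = sim$model,
                          lesion_mask = ph$label$values == 1,
                          true_ratio = 4.95, bounds = c(1.5, 11),
                          restrict = body)
    expect_equal(cal$fwhm_mm, fw, tolerance = 0.5 / fw)
  }
  # bounds that exclude the truth are refused
  sim <- simulate_acquisition(ph, 8, 0.2, 5e5, seed = 1L, noise = FALSE,
                              n_angles = 60L)
  expect_error(calibrate_fwhm(sim$counts, model = sim$model,
                              lesion_mask = ph$label$values == 1,
                              true_ratio = 4.95, bounds = c(1.5, 4),
                              restrict = body),
               "no minimum")
})
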