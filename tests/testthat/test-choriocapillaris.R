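test_that("slab projection averages exactly the requested depth run", {
  vol <- array(7, c(6, 6, 30))
  bm <- matrix(5L, 6, 6)
  ef <- project_cc_slab(vol, bm, slab_spec(thickness_um = 20), axial_um_per_px = 2)
  expect_true(all(ef$image == 7))

  # bright only within 20 um below BM
  vol2 <- array(10, c(6, 6, 30))
  for (k in 5:14) vol2[, , k] <- 200
  ef2 <- project_cc_slab(vol2, bm, slab_spec(thickness_um = 20), axial_um_per_px = 2)
  expect_true(all(ef2$image == 200))

  # doubling the thickness over a two-layer volume averages the layers
  ef3 <- project_cc_slab(vol2, bm, slab_spec(thickness_um = 40), axial_um_per_px = 2)
  expect_true(all(ef3$image == 105))

  bm_bad <- bm
  bm_bad[2, 3] <- 28L
  expect_error(project_cc_slab(vol, bm_bad, slab_spec(thickness_um = 20), 2),
               "row 2, col 3")
})

test_that("compensation with a uniform reference and no projections is identity", {
  an <- generate_cc_enface(angio_params(seed = 4, target_fd_fraction = 0.05))
  comp <- compensate_enface(an, matrix(150, 512, 512))
  expect_identical(comp$image, an$image)
  expect_error(compensate_enface(an, matrix(0, 512, 512)), "non-positive")
  expect_error(compensate_enface(an, matrix(150, 100, 100)), "dimensions")
})

test_that("shadow compensation restores the unshadowed intensities", {
  an <- generate_cc_enface(angio_params(seed = 12, target_fd_fraction = 0.05,
                                        shadow_attenuation = 0.5))
  comp <- compensate_enface(an, an$truth$reference)
  # deep inside the shadow (away from the smoothing transition zone)
  core <- EBImage::erode(1 * (an$truth$shadow_map < 1),
                         EBImage::makeBrush(61, "disc")) > 0.5
  ok <- core & !an$truth$deficit_mask
  expect_gt(sum(ok), 1000)
  expect_lt(mean(abs(comp$image[ok] - as.numeric(an$truth$unshadowed[ok]))), 5)
})

test_that("projection stripes are suppressed to background level", {
  an <- generate_cc_enface(angio_params(seed = 21, target_fd_fraction = 0.05,
                                        n_projection_vessels = 3L))
  comp <- compensate_enface(an, an$truth$reference, an$truth$projection_mask)
  prj <- an$truth$projection_mask
  bg <- !prj & !an$truth$deficit_mask
  q99 <- quantile(an$image[bg], 0.99)
  expect_gt(max(an$image[prj]), q99)          # artifact present before
  expect_lte(max(comp$image[prj]), q99)       # suppressed after
})

test_that("flow-deficit percentage hits its analytic extremes", {
  uni <- enface_angio(matrix(180, 512, 512), 3000 / 512)
  expect_equal(compute_ccfd(uni)$ccfd_pct, 0)
  zero <- enface_angio(matrix(0, 512, 512), 3000 / 512)
  expect_equal(compute_ccfd(zero)$ccfd_pct, 100)
  small <- enface_angio(matrix(200, 100, 100), 3000 / 512)
  expect_error(compute_ccfd(small), "leaves")
  expect_error(fd_threshold_spec(sigma_ref = 0), "sigma_ref")
})

test_that("the ROI pixel count matches the continuous circle area", {
  r <- compute_ccfd(enface_angio(matrix(180, 512, 512), 3000 / 512))
  expect_lt(abs(r$n_roi_px - pi * r$roi$radius_px^2) / (pi * r$roi$radius_px^2),
            0.01)
  expect_true(all(which(r$deficit_mask) %in% which(
    chorovasc:::circle_mask(512, 512, r$roi$center, r$roi$radius_px))))
})

test_that("CcFD recovers the seeded deficit fraction under clean separation", {
  errs <- c()
  for (tg in c(0.02, 0.05, 0.10, 0.20)) for (s in 1:3) {
    an <- generate_cc_enface(angio_params(seed = s + round(1000 * tg),
                                          target_fd_fraction = tg))
    r <- compute_ccfd(an)
    errs <- c(errs, r$ccfd_pct - 100 * an$truth$realized_fd_fraction)
  }
  expect_lt(max(abs(errs)), 1.5)
})

test_that("CcFD is non-decreasing in the threshold multiplier and sigma", {
  an <- generate_cc_enface(angio_params(seed = 77, target_fd_fraction = 0.10,
                                        noise_sd = 20))
  cc_m <- vapply(c(0.5, 1, 1.5, 2, 3, 4),
                 function(m) compute_ccfd(an, fd_threshold_spec(multiplier = m))$ccfd_pct,
                 numeric(1))
  expect_true(all(diff(cc_m) >= 0))
  cc_s <- vapply(c(10, 20, 30, 45, 60),
                 function(s) compute_ccfd(an, fd_threshold_spec(sigma_ref = s))$ccfd_pct,
                 numeric(1))
  expect_true(all(diff(cc_s) >= 0))
})

test_that("compensation always moves CcFD toward the no-shadow truth", {
  for (att in c(0.15, 0.25)) for (s in 1:3) {
    an <- generate_cc_enface(angio_params(seed = 300 + s, target_fd_fraction = 0.08,
                                          shadow_attenuation = att))
    truth <- 100 * an$truth$realized_fd_fraction
    raw <- compute_ccfd(an)$ccfd_pct
    comp <- compute_ccfd(compensate_enface(an, an$truth$reference))$ccfd_pct
    expect_lt(abs(comp - truth), abs(raw - truth))
  }
})
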