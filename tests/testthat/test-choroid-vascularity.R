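test_that("magnification scale is the Bennett axial-length ratio", {
  expect_equal(magnification_scale(24.385, 24.385), 1.0)
  # direct arithmetic: (26.205 - 1.82) / (24.385 - 1.82)
  expect_equal(magnification_scale(26.205, 24.385), 24.385 / 22.565,
               tolerance = 1e-12)
  expect_gt(magnification_scale(26.0), magnification_scale(24.0))
  expect_error(magnification_scale(12), "15")
  expect_error(magnification_scale(25, 45), "40")
})

test_that("niblack binarization honours its tie-break and mask contracts", {
  img <- matrix(100, 80, 80)
  mask <- matrix(TRUE, 80, 80)
  # constant image: SD = 0, threshold = mean; ties are stroma
  expect_false(any(niblack_binarize(img, mask, niblack_params(k = 0))))
  expect_false(any(niblack_binarize(img, mask, niblack_params(k = -0.2))))
  expect_error(niblack_binarize(img, matrix(FALSE, 80, 80)), "empty")
  expect_error(niblack_binarize(img, mask, niblack_params(window_px = 101L)),
               "fit")
  expect_error(niblack_params(window_px = 50L), "odd")
})

test_that("niblack equals the global threshold on a noise-free disk scene", {
  n <- 120
  img <- matrix(200, n, n)
  disks <- matrix(FALSE, n, n)
  for (ctr in list(c(30, 30), c(30, 90), c(90, 30), c(90, 60), c(60, 95))) {
    d <- outer((seq_len(n) - ctr[1])^2, (seq_len(n) - ctr[2])^2, `+`) <= 16
    disks <- disks | d
  }
  img[disks] <- 40
  mask <- matrix(TRUE, n, n)
  got <- niblack_binarize(img, mask, niblack_params(window_px = 119L, k = 0))
  # oracle: brute-force global threshold at the global masked mean
  oracle <- img < mean(img)
  expect_identical(got, oracle)
  expect_identical(got, disks)
})

test_that("niblack is invariant to positive intensity scaling", {
  set.seed(8)
  img <- matrix(runif(60 * 60, 20, 220), 60, 60)
  mask <- matrix(TRUE, 60, 60)
  base <- niblack_binarize(img, mask, niblack_params(window_px = 21L))
  for (cc in c(0.25, 3)) {
    expect_identical(niblack_binarize(img * cc, mask,
                                      niblack_params(window_px = 21L)), base)
  }
})

test_that("choroid metrics recover exact areas on a rectangular band", {
  n_col <- 600L
  b <- flat_boundaries(n_col, upper = 50L, thickness_px = 100L)
  g <- scan_geometry(lateral_um_per_px = 5.859375, axial_um_per_px = 3,
                     fovea_col = 301L)
  empty <- matrix(FALSE, 200, n_col)
  m <- compute_choroid_metrics(b, g, empty, roi_width_mm = 3)
  # 3 mm x 300 um rectangle
  expect_equal(m$TCA, 3000 * 300)
  expect_equal(m$LA, 0)
  expect_equal(m$SA, m$TCA)
  expect_equal(m$CVI, 0)
  expect_equal(m$SFCT, 300)
  # full-lumen band
  full <- chorovasc:::boundaries_to_mask(b, 200)
  m2 <- compute_choroid_metrics(b, g, full, roi_width_mm = 3)
  expect_equal(m2$CVI, 100)
  expect_equal(m2$TCA, m2$LA)
  expect_error(compute_choroid_metrics(b, g, empty, roi_width_mm = 8), "ROI")
})

test_that("area additivity and the cohort table totals are consistent", {
  adult <- choroid_metrics(SFCT = 267.2, LA = 990.0e3, SA = 589.4e3)
  expect_equal(adult$TCA, 1579.4e3)
  child <- choroid_metrics(SFCT = 255.9, LA = 919.6e3, SA = 587.8e3)
  expect_equal(child$TCA, 1507.4e3)
  expect_equal(adult$CVI, 100 * 990.0 / 1579.4)
})

test_that("physical areas are invariant to the magnification correction", {
  # the same 3-mm of tissue measured in a longer eye (coarser true pixels)
  n_col <- 700L
  b <- flat_boundaries(n_col)
  empty <- matrix(FALSE, 200, n_col)
  m_ref <- compute_choroid_metrics(
    b, scan_geometry(5.859375, 3, fovea_col = 351L), empty, roi_width_mm = 3)
  m_long <- compute_choroid_metrics(
    b, scan_geometry(5.859375, 3, fovea_col = 351L, al_mm = 26.2),
    empty, roi_width_mm = 3)
  expect_lt(abs(m_long$TCA - m_ref$TCA) / m_ref$TCA, 0.005)
  expect_equal(m_long$SFCT, m_ref$SFCT)   # axial spacing is AL-independent
  # per-pixel area itself scales linearly with the factor
  s <- magnification_scale(26.2, 24.385)
  px_long <- m_long$TCA / (5.859375 * s * 3)
  px_ref <- m_ref$TCA / (5.859375 * 3)
  expect_equal(m_long$TCA / px_long, s * m_ref$TCA / px_ref, tolerance = 1e-9)
})

test_that("meridian averaging is a commutative field-wise mean", {
  mv <- choroid_metrics(SFCT = 300, LA = 900e3, SA = 600e3, meridian = "vertical")
  mh <- choroid_metrics(SFCT = 280, LA = 1000e3, SA = 500e3, meridian = "horizontal")
  mv$CVI <- 60
  mh$CVI <- 64
  a <- average_meridians(mv, mh)
  expect_equal(a$CVI, 62)           # mean of ratios, not ratio of means
  expect_equal(a$SFCT, 290)
  expect_equal(a$TCA, a$LA + a$SA)
  expect_identical(unclass(a), unclass(average_meridians(mh, mv)))
  expect_identical(unclass(average_meridians(mv, mv))[c("SFCT", "LA", "SA", "TCA", "CVI")],
                   unclass(mv)[c("SFCT", "LA", "SA", "TCA", "CVI")])
  expect_error(average_meridians(a, mv), "single-meridian")
})

test_that("the structural pipeline recovers CVI and TCA from synthetic scenes", {
  errs_cvi <- c()
  errs_tca <- c()
  targets <- rep(c(0.45, 0.55, 0.65, 0.75), each = 2)
  for (i in seq_along(targets)) {
    sc <- generate_bscan_scene(
      scene_params(image_width_px = 1200L, image_height_px = 300L,
                   target_lumen_fraction = targets[i], seed = 100 + i),
      roi_width_mm = 6)
    m <- quantify_scene(sc)
    errs_cvi <- c(errs_cvi, m$CVI - sc$truth$true_CVI)
    errs_tca <- c(errs_tca, (m$TCA - sc$truth$true_TCA) / sc$truth$true_TCA)
  }
  expect_lt(max(abs(errs_cvi)), 2.5)
  expect_lt(max(abs(errs_tca)), 0.02)
})
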