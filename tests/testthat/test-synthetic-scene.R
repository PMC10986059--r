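test_that("a scene without vessels has zero luminal area and zero CVI", {
  sc <- gen_small_scene(seed = 3, target = 0)
  expect_equal(sc$truth$true_LA, 0)
  expect_equal(sc$truth$true_CVI, 0)
  expect_false(any(sc$truth$lumen_mask))
  expect_gt(sc$truth$true_TCA, 0)
})

test_that("identical parameters and seed give bit-identical scenes", {
  a <- gen_small_scene(seed = 42, target = 0.55)
  b <- gen_small_scene(seed = 42, target = 0.55)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  c <- gen_small_scene(seed = 43, target = 0.55)
  expect_false(identical(a$image, c$image))
})

test_that("truth areas partition exactly and stay in range across seeds", {
  for (seed in 1:6) {
    tg <- c(0.45, 0.55, 0.65, 0.7, 0.75, 0.6)[seed]
    sc <- gen_small_scene(seed = seed, target = tg)
    expect_identical(sc$truth$true_TCA, sc$truth$true_LA + sc$truth$true_SA)
    expect_gte(sc$truth$true_CVI, 0)
    expect_lte(sc$truth$true_CVI, 100)
    expect_true(all(sc$boundaries$upper_px < sc$boundaries$lower_px))
    expect_lt(abs(sc$truth$realized_lumen_fraction - tg), 0.05)
  }
})

test_that("mean realized lumen fraction tracks the 0.6 target over many seeds", {
  fr <- vapply(1:50, function(s) {
    p <- scene_params(image_width_px = 500L, image_height_px = 200L,
                      choroid_thickness_um = 220,
                      target_lumen_fraction = 0.6, seed = s)
    generate_bscan_scene(p, roi_width_mm = 2)$truth$realized_lumen_fraction
  }, numeric(1))
  expect_gt(mean(fr), 0.55)
  expect_lt(mean(fr), 0.65)
})

test_that("realized fraction is non-decreasing over an increasing target grid", {
  grid <- c(0.15, 0.3, 0.45, 0.6, 0.75)
  fr <- vapply(grid, function(tg)
    gen_small_scene(seed = 9, target = tg)$truth$realized_lumen_fraction,
    numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("invalid scene parameters are rejected with explicit errors", {
  expect_error(scene_params(target_lumen_fraction = 0.95), "unreachable")
  expect_error(scene_params(target_lumen_fraction = -0.1), "\\[0, 1\\]")
  expect_error(scene_params(stroma_mean = 50, lumen_mean = 60), "stroma_mean")
  expect_error(scene_params(speckle_shape = 0), "speckle_shape")
  expect_error(scene_params(vessel_radius_range_um = c(80, 30)), "increasing")
  expect_error(scene_params(image_height_px = 60L,
                            choroid_thickness_um = 400), "fit")
})
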