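# Small, fast parameter sets used across the unit tests. The full-scale
# acquisition geometry (2048 px / 12 mm lines, 6-mm ROI) is exercised in
# test-acceptance.R; unit tests use shorter scan lines with a 3-mm ROI so
# the suite stays quick.

small_scene <- function(seed, target = 0.6, ...) {
  scene_params(image_width_px = 700L, image_height_px = 240L,
               choroid_thickness_um = 240,
               target_lumen_fraction = target, seed = seed, ...)
}

gen_small_scene <- function(seed, target = 0.6, roi_width_mm = 3, ...) {
  generate_bscan_scene(small_scene(seed, target, ...), roi_width_mm = roi_width_mm)
}

# quantify one scene with the default structural pipeline
quantify_scene <- function(scene, despeckle_radius = 1L,
                           nib = niblack_params(), roi_width_mm = NULL) {
  if (is.null(roi_width_mm)) roi_width_mm <- scene$roi_width_mm
  img <- despeckle(scene$image, despeckle_radius)
  band <- chorovasc:::boundaries_to_mask(scene$boundaries, nrow(img))
  lum <- niblack_binarize(img, band, nib)
  compute_choroid_metrics(scene$boundaries, scene$geometry, lum,
                          roi_width_mm = roi_width_mm)
}

# flat-boundary geometry for exact-area tests
flat_boundaries <- function(n_col, upper = 50L, thickness_px = 100L) {
  choroid_boundaries(rep(upper, n_col), rep(upper + thickness_px, n_col))
}
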