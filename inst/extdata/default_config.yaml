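# Default pipeline configuration: a small imaging track (2 subjects per
# cohort, one 20-min visit) plus the full 30-per-group cohort table.
seed: 1
out_dir: chorovasc_run
n_imaging_subjects_per_group: 2
visit_durations: [20, 40, 60]
scene:
  image_width_px: 1200
  image_height_px: 320
  choroid_thickness_um: 260
angio:
  image_size_px: 512
despeckle_radius: 1
niblack:
  window_px: 51
  k: -0.2
fd_threshold:
  sigma_ref: 30
  multiplier: 1.5
slab:
  offset_um: 0
  thickness_um: 20
roi_width_mm: 6.0
circle_diameter_mm: 2.5
reference_al_mm: 24.385
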