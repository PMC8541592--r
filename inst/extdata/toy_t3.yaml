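# Miniature source/target pair with both covariate shift (blue -> red,
# halo on) and label gap (counts [3,8] -> [6,12], smaller blobs).
n_images: 12
split_fracs: [0.55, 0.20, 0.25]
source:
  image_size: 64
  count_range: [3, 8]
  blob_radius_range: [3.0, 5.0]
  blob_color: [0.25, 0.35, 0.90]
  color_jitter_sd: 0.05
  halo: false
  background_noise_std: 0.02
  seed: 11
target:
  appearance_shift:
    blob_color: [0.90, 0.25, 0.20]
    halo: true
  label_gap_shift:
    count_range: [6, 12]
    blob_radius_range: [2.0, 3.5]
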