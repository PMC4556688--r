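# fibrilquant pipeline configuration (flat key: value)
calibration_nm_per_px: 1
block_size_px: 51
threshold_offset: 0.01
opening_radius_px: 2
max_eccentricity: 0.90
min_area_px2: 30
window_size_px: 300
n_windows: 200
polarity: bright_objects
seed: 11
sim_density_per_window: 18
sim_diam_mean_nm: 40.67
sim_diam_sd_nm: 2
sim_min_gap_nm: 4
sim_n_artifacts: 5
sim_image_px: 1024
sim_noise_sd: 0.05
sim_blur_px: 1
sim_peak_temp_C: 71.99
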