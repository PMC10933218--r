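{
  "seed": 20,
  "output_dir": "vatprofiler-demo",
  "groups": {
    "label": ["CD", "UC", "control"],
    "n_phantoms": [4, 4, 4],
    "concentration": [0.6, 0.35, 0.25],
    "concentration_sd": [0.15, 0.12, 0.08],
    "vat_volume_mean_cm3": [1200, 1400, 1700],
    "vat_volume_sd_cm3": [150, 150, 150]
  },
  "phantom": {
    "grid_shape": [120, 92, 52],
    "voxel_spacing_mm": [2, 2, 6],
    "body_radius_mm": [110, 78]
  },
  "segmentation": {
    "window_low_hu": -190,
    "window_high_hu": -30,
    "shell_voxels": 2
  },
  "slice_plan": {
    "n_per_vertebra": 5,
    "n_pelvic": 10
  }
}
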