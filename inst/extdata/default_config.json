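{
  "experiment": "g00_active",
  "seed": 1,
  "paths": {
    "out": "runs/g00_active"
  },
  "geometry": {
    "pixels_per_side": 1024,
    "pixel_size_um": 0.2804,
    "n_z": 5,
    "z_step_um": 1,
    "z_range_um": 2,
    "n_timepoints": 12,
    "dt_min": 5
  },
  "n_positions": 7,
  "gel": {
    "cellulose_pct": 0,
    "pectin_pct": 1.5,
    "particle_density": 0,
    "particle_size_um": [5, 30],
    "particle_shape": "ellipse",
    "binding_k_on": 0,
    "label": "g00"
  },
  "enzyme": {
    "state": "active",
    "d_base_um2_s": 5,
    "catalytic_factor": 10,
    "cellulose_factor": 7.33333333333333,
    "n_residues": 314
  },
  "source": {
    "channel_width_um": 500,
    "c0": 1,
    "replenished": false,
    "loading_length_um": 414.240450012432
  },
  "optics": {
    "gain_counts_per_conc": 1080,
    "ill_min": 0.7,
    "bkg_level_counts": 100,
    "read_noise_sd_counts": 8,
    "shot_noise": true,
    "defocus_sd_um_per_um": 0.5,
    "bit_depth": 16
  },
  "simulate": {
    "grid_um": 4,
    "dt_s": 2,
    "method": "adi",
    "domain_y_um": 300,
    "n_dark": 10
  },
  "preprocess": {
    "filter_size": 105,
    "normalize_ill": true,
    "write_corrected": false
  },
  "sampler": {
    "type": "random_line",
    "exclusion": "none",
    "auto_threshold": 0.2,
    "max_overlap": 0.05,
    "max_redraws": 50
  },
  "kinetics": {
    "positions": [0, 1, 3, 6],
    "times": [0, 15, 30, 45],
    "threshold_fraction": 0.05
  }
}
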