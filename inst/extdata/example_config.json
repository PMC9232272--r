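{
  "seed": 1,
  "out_dir": "out",
  "protocol": {
    "n_depth": 512,
    "n_fast": 256,
    "n_slow": 128,
    "axial_pitch_um": 3.6,
    "fast_pitch_um": 39.0625,
    "slow_pitch_um": 85.9375,
    "bscan_rate_hz": 100,
    "n_refs": 3,
    "alpha": 0.33
  },
  "preprocess": {
    "gauss_size": 10,
    "gauss_sigma": 4,
    "mean_filter_len": 40,
    "refine_window": 15,
    "fit_order": 4,
    "threshold_window": 64,
    "threshold_offset": 0,
    "border_crop": 12
  },
  "lateral": {
    "search_px": 50,
    "crop_px": 12
  },
  "synth": {
    "surface": {
      "kind": "quartic",
      "apex_depth_px": 215,
      "ripple_amp_um": 4
    },
    "noise": {
      "speckle": true,
      "band_thickness_px": 2,
      "psf_sigma_px": 1.5
    },
    "motion": {
      "kind": "sinusoid",
      "params": {
        "axial": { "amp_um": 700, "freq_hz": 1 }
      }
    }
  },
  "theory": {
    "sigma": 123,
    "m": 1023,
    "grid_step": 0.009765625
  }
}
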