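{
  "band": [0.0078, 0.1],
  "n_freq": 8,
  "mar_order": 16,
  "v_a": 0.015625,
  "v_self": 0.00390625,
  "v_fluct": 0.015625,
  "v_hemo": 0.00390625,
  "modes": "all",
  "bmr_strategy": "single-pass",
  "removal_var": 1e-08,
  "sim": {
    "n": 6,
    "density": 0.4,
    "coupling_scale": 0.25,
    "duration": 1024,
    "TR": 2,
    "noise_frac": 0.1
  },
  "seed": 1
}
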