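{
  "n_subjects": {
    "control": 13,
    "mild_dai": 13,
    "severe_dai": 15
  },
  "effects": "default",
  "bands": {
    "broadband": [2, 20],
    "slow": [2, 7],
    "alpha": [8, 13],
    "beta": [14, 19]
  },
  "k_max": 8,
  "epoch_seconds": 60,
  "hemisphere_asymmetry": 0.04,
  "subject_sd": 0.03,
  "fs": 250,
  "stimulus_duration_s": 10,
  "repetitions": 12,
  "rest_duration_s": 90,
  "gap_s": 2,
  "amplitude_uv": 15,
  "response_set": "state_means",
  "posthoc_method": "games_howell",
  "family_residual": 0.05,
  "seed": 20200827,
  "out_dir": "fractaleeg_run"
}
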