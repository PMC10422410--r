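{
  "n_per_group": 10,
  "profiles": {
    "low": {
      "dwell_mean_ms": 250,
      "dwell_sd_ms": 50,
      "transit_ms": 150,
      "stray_prob": 0.02,
      "revisit_prob": 0.01,
      "slow_factor": 1,
      "noise_px": 5
    },
    "medium": {
      "dwell_mean_ms": 250,
      "dwell_sd_ms": 50,
      "transit_ms": 150,
      "stray_prob": 0.15,
      "revisit_prob": 0.15,
      "slow_factor": 1.5,
      "noise_px": 5
    },
    "high": {
      "dwell_mean_ms": 250,
      "dwell_sd_ms": 50,
      "transit_ms": 150,
      "stray_prob": 0.35,
      "revisit_prob": 0.35,
      "slow_factor": 2.5,
      "noise_px": 5
    }
  },
  "seed": 1
}
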