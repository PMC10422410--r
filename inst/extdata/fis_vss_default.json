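{
  "name": "visual_search_speed",
  "input_names": ["FH1", "FH2"],
  "norm": {
    "scale1": 65,
    "scale2": 180000
  },
  "input1": {
    "name": "FH1_norm",
    "universe": [0, 1],
    "sets": {
      "low": [0, 0, 0.3, 0.5],
      "medium": [0.1, 0.3, 0.7, 0.9],
      "high": [0.5, 0.7, 1, 1]
    }
  },
  "input2": {
    "name": "FH2_norm",
    "universe": [0, 1],
    "sets": {
      "low": [0, 0, 0.3, 0.5],
      "medium": [0.1, 0.3, 0.7, 0.9],
      "high": [0.5, 0.7, 1, 1]
    }
  },
  "output": {
    "name": "visual_search_speed",
    "universe": [0, 1],
    "sets": {
      "low": [0, 0, 0.3, 0.5],
      "medium": [0.1, 0.3, 0.7, 0.9],
      "high": [0.5, 0.7, 1, 1]
    }
  },
  "rules": {
    "in1": ["low", "low", "medium", "medium", "low", "high", "medium", "high", "high"],
    "in2": ["low", "medium", "low", "medium", "high", "low", "high", "medium", "high"],
    "out": ["high", "high", "high", "medium", "medium", "medium", "low", "low", "low"]
  }
}
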