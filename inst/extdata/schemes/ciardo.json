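{
  "name": "ciardo",
  "schema_version": 1,
  "description": "Median-value three-level scheme over DSC, centre-of-mass distance and average Hausdorff distance.",
  "indexes": {
    "dsc": {"direction": "higher", "cutpoints": [0.6, 0.8]},
    "cmd": {"direction": "lower", "cutpoints": [0.2, 0.5]},
    "ahd": {"direction": "lower", "cutpoints": [0.15, 0.40]}
  }
}
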