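{
  "combined": {"group": "combined", "a_mm": 23.60, "b_mm": -5.60, "c_per_year": 0.30},
  "EA":       {"group": "EA",       "a_mm": 23.69, "b_mm": -6.91, "c_per_year": 0.33},
  "nonEA":    {"group": "nonEA",    "a_mm": 23.54, "b_mm": -4.15, "c_per_year": 0.24}
}
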