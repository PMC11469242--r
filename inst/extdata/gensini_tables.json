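{
  "description": "Default adjusted Gensini scoring tables: severity points per stenosis category and coronary-segment multipliers. The ramus intermedius is scored with multiplier 1.",
  "severity_points": {
    "25": 1,
    "50": 2,
    "75": 4,
    "90": 8,
    "99": 16,
    "100": 32
  },
  "segment_multipliers": {
    "left_main": 5,
    "lad_proximal": 2.5,
    "lad_mid": 1.5,
    "lad_distal": 1,
    "first_diagonal": 1,
    "second_diagonal": 0.5,
    "lcx_proximal": 2.5,
    "lcx_distal": 1,
    "obtuse_marginal": 1,
    "posterolateral": 0.5,
    "rca_proximal": 1,
    "rca_mid": 1,
    "rca_distal": 1,
    "posterior_descending": 1,
    "ramus_intermedius": 1
  }
}
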