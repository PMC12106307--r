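{
  "note": "Synthetic calibrated fixture: transition hazards solved so the deterministic base case reproduces the published cost/QALY totals; not the (unpublished) source transition tables.",
  "achieved": {
    "cost_mono": 529928.56,
    "qalys_mono": 1.47999999999831,
    "cost_combo": 650629.56,
    "qalys_combo": 2.01999999999999
  },
  "targets": {
    "cost_mono": 529928.56,
    "qalys_mono": 1.48,
    "cost_combo": 650629.56,
    "qalys_combo": 2.02,
    "tolerance": 0.001
  },
  "max_rel_error": 1.14142929342543e-12,
  "converged": true,
  "settings": {
    "onset_hazard": {
      "mono": 0.02,
      "combo": 0.02
    },
    "excess_ratio": [
      3
    ],
    "mix_weights": [
      1,
      1,
      1,
      1,
      1,
      1
    ],
    "cost_multiplier": true,
    "death_hazard": {
      "mono": 0.0286510788909807,
      "combo": 0.0161245080886922
    }
  }
}
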