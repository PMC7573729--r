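{
  "classes": {
    "qa": { "n_tips": 8, "omega": 0.2, "regime": "gradual_bm" },
    "qb": { "n_tips": 8, "omega": 0.2, "regime": "rapid_partition" },
    "rs": { "n_tips": 8, "omega": 0.2, "regime": "neo_burst",
            "regime_params": { "burst_edges": [1, 6], "sigma2": 1 },
            "omega_burst": 1 }
  },
  "n_codons": 300,
  "n_tissues": 12,
  "lambda": 1,
  "kappa": 2,
  "tree_scale": 0.3,
  "seed": 20
}
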