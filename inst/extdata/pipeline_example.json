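{
  "seed": 1,
  "output_dir": "reports",
  "targets": { "E1": 20, "E2": 500, "E1_range": [13.6, 25.8] },
  "moduli": { "n_runs": 10, "n_boot": 10, "psi0": [0.30, 0.40, 0.60] },
  "mixtures": [
    {
      "material": "SOFT-A", "dilution_pct": 5,
      "synthetic": {
        "kind": "blatz", "alpha": 1.64, "gamma": 19.52,
        "n_replicates": 5, "noise_rel": 0.02
      }
    },
    {
      "material": "STIFF-B", "dilution_pct": 0,
      "synthetic": {
        "kind": "blatz", "alpha": 1.05, "gamma": 144.5,
        "n_replicates": 5, "noise_rel": 0.02
      }
    }
  ]
}
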