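{
  "seed": 1,
  "verbose": false,
  "fish": {
    "n_cells": 5000,
    "condition": "hypoxia",
    "genotype": "NTC",
    "negative_control": "NEG_CTRL@Opal570",
    "quantile": 0.99
  },
  "hetero": { "target_fraction": 0.5 },
  "correlate": {
    "pairs": [
      ["POLR2A@Opal570", "UBC@Opal650"],
      ["HIF1A@Opal570", "CAIX@Opal570"],
      ["EPAS1@Opal650", "SERPINE1@Opal650"]
    ]
  },
  "sc": {
    "n_cells": 150,
    "capture_efficiency": 0.05,
    "n_pcs": 15,
    "positivity_genes": ["HIF1T_01", "HIF2T_01"]
  }
}
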