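[
  {"fixative_pct": 4, "agent": "Gd-DTPA",    "tissue": "CC",       "T10": 707, "r1": 0.120, "sigma1": 93.4, "T20": 35.8, "r2": 0.703, "sigma2": 3.50},
  {"fixative_pct": 4, "agent": "Gd-DTPA",    "tissue": "cortex",   "T10": 706, "r1": 0.149, "sigma1": 83.6, "T20": 36.9, "r2": 0.709, "sigma2": 4.13},
  {"fixative_pct": 4, "agent": "Gd-DTPA",    "tissue": "thalamus", "T10": 643, "r1": 0.127, "sigma1": 78.6, "T20": 34.0, "r2": 0.672, "sigma2": 3.31},
  {"fixative_pct": 2, "agent": "Gd-DTPA",    "tissue": "CC",       "T10": 876, "r1": 0.109, "sigma1": 94.0, "T20": 45.0, "r2": 0.444, "sigma2": 8.20},
  {"fixative_pct": 2, "agent": "Gd-DTPA",    "tissue": "cortex",   "T10": 896, "r1": 0.167, "sigma1": 90.6, "T20": 46.8, "r2": 0.801, "sigma2": 7.75},
  {"fixative_pct": 2, "agent": "Gd-DTPA",    "tissue": "thalamus", "T10": 870, "r1": 0.172, "sigma1": 75.2, "T20": 40.9, "r2": 0.813, "sigma2": 6.18},
  {"fixative_pct": 2, "agent": "gadobutrol", "tissue": "CC",       "T10": 354, "r1": 0.267, "sigma1": 67.1, "T20": 30.4, "r2": 0.438, "sigma2": 2.90},
  {"fixative_pct": 2, "agent": "gadobutrol", "tissue": "cortex",   "T10": 385, "r1": 0.325, "sigma1": 21.7, "T20": 31.2, "r2": 0.516, "sigma2": 1.80},
  {"fixative_pct": 2, "agent": "gadobutrol", "tissue": "thalamus", "T10": 353, "r1": 0.301, "sigma1": 39.5, "T20": 28.7, "r2": 0.603, "sigma2": 2.31}
]
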