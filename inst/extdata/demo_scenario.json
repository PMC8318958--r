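{
  "composition": {
    "PC": 0.30, "PE": 0.22, "PG": 0.10, "UNK1": 0.08, "PA": 0.07,
    "SM": 0.06, "LPI": 0.05, "UNK2": 0.05, "LPC": 0.04, "LPA": 0.03
  },
  "mass_mg": 8,
  "age_hours": 48,
  "adduct": null,
  "adduct_mg": 10,
  "noise_sigma": 0.4,
  "seed": 42,
  "lb": 1.5,
  "zf": 32768,
  "shape_mode": "pseudo_voigt",
  "min_snr": 3,
  "min_frac_pct": 0.01,
  "basis": "per_phosphorus",
  "tolerance": 0.02,
  "library_path": null
}
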