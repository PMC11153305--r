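[
  {"name": "metformin",   "class": "biguanide",      "max_daily_dose": 3000, "dose_unit": "mg", "adjustment_factor": 1.5},
  {"name": "gliclazide",  "class": "sulfonylurea",   "max_daily_dose": 240,  "dose_unit": "mg", "adjustment_factor": 1.5},
  {"name": "glimepiride", "class": "sulfonylurea",   "max_daily_dose": 6,    "dose_unit": "mg", "adjustment_factor": 1.5},
  {"name": "sitagliptin", "class": "DPP4 inhibitor", "max_daily_dose": 100,  "dose_unit": "mg", "adjustment_factor": 0.75},
  {"name": "liraglutide", "class": "GLP-1 agonist",  "max_daily_dose": 1.8,  "dose_unit": "mg", "adjustment_factor": 1.0},
  {"name": "insulin_glargine", "class": "insulin",   "max_daily_dose": 100,  "dose_unit": "IU", "adjustment_factor": 2.5}
]
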