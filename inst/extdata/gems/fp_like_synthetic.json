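{
  "id": "fp_like_synthetic",
  "description": "Synthetic toy network (not a curated genome-scale model) expressing the butyrate producer's qualitative pattern: no mucin-derived sugar uptake; serine, threonine and uracil are individually essential; acetate can be taken up and converted to secreted butyrate without affecting growth.",
  "metabolites": [
    {"id": "ser_e"}, {"id": "thr_e"}, {"id": "ura_e"}, {"id": "ac_e"},
    {"id": "but_e"}, {"id": "pyr"}, {"id": "succoa"}, {"id": "nuc"}
  ],
  "reactions": [
    {"id": "EX_ser_e", "metabolites": {"ser_e": -1}, "lower_bound": -6, "upper_bound": 0},
    {"id": "EX_thr_e", "metabolites": {"thr_e": -1}, "lower_bound": -4, "upper_bound": 0},
    {"id": "EX_ura_e", "metabolites": {"ura_e": -1}, "lower_bound": -2, "upper_bound": 0},
    {"id": "EX_ac_e", "metabolites": {"ac_e": -1}, "lower_bound": -3, "upper_bound": 0},
    {"id": "EX_but_e", "metabolites": {"but_e": -1}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "CAT_SER", "metabolites": {"ser_e": -1, "pyr": 1}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "CAT_THR", "metabolites": {"thr_e": -1, "succoa": 1}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "CAT_URA", "metabolites": {"ura_e": -1, "nuc": 1}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "BUT_FORM", "metabolites": {"ac_e": -1, "but_e": 1}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "BIOMASS", "metabolites": {"pyr": -0.5, "succoa": -0.3, "nuc": -0.1}, "lower_bound": 0, "upper_bound": 1000, "objective_coefficient": 1}
  ]
}
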