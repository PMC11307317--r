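{
  "id": "am_like_synthetic",
  "description": "Synthetic toy network (not a curated genome-scale model) expressing the mucin specialist's qualitative essentiality pattern: N-acetylglucosamine, asparagine and threonine each feed a distinct biomass precursor and are individually essential; serine is catabolized to secreted acetate and is dispensable.",
  "metabolites": [
    {"id": "nacgam_e"}, {"id": "asn_e"}, {"id": "thr_e"}, {"id": "ser_e"},
    {"id": "ac_e"}, {"id": "f6p"}, {"id": "oaa"}, {"id": "succoa"}
  ],
  "reactions": [
    {"id": "EX_nacgam_e", "metabolites": {"nacgam_e": -1}, "lower_bound": -10, "upper_bound": 0},
    {"id": "EX_asn_e", "metabolites": {"asn_e": -1}, "lower_bound": -5, "upper_bound": 0},
    {"id": "EX_thr_e", "metabolites": {"thr_e": -1}, "lower_bound": -5, "upper_bound": 0},
    {"id": "EX_ser_e", "metabolites": {"ser_e": -1}, "lower_bound": -5, "upper_bound": 0},
    {"id": "EX_ac_e", "metabolites": {"ac_e": -1}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "CAT_NACGAM", "metabolites": {"nacgam_e": -1, "f6p": 1}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "CAT_ASN", "metabolites": {"asn_e": -1, "oaa": 1}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "CAT_THR", "metabolites": {"thr_e": -1, "succoa": 1}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "CAT_SER", "metabolites": {"ser_e": -1, "ac_e": 1}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "BIOMASS", "metabolites": {"f6p": -0.5, "oaa": -0.3, "succoa": -0.2}, "lower_bound": 0, "upper_bound": 1000, "objective_coefficient": 1}
  ]
}
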