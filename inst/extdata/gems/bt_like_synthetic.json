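{
  "id": "bt_like_synthetic",
  "description": "Synthetic toy network (not a curated genome-scale model) expressing the generalist's qualitative pattern: a wide substrate range with no essential single substrate; only aspartate and N-acetylglucosamine depletion significantly reduce growth, the redundant sugars and glutamine are dispensable. A biomass capacity cap leaves slack on both precursor pools.",
  "metabolites": [
    {"id": "nacgam_e"}, {"id": "glca_e"}, {"id": "glcb_e"}, {"id": "asp_e"},
    {"id": "gln_e"}, {"id": "f6p"}, {"id": "oaa"}
  ],
  "reactions": [
    {"id": "EX_nacgam_e", "metabolites": {"nacgam_e": -1}, "lower_bound": -8, "upper_bound": 0},
    {"id": "EX_glca_e", "metabolites": {"glca_e": -1}, "lower_bound": -2, "upper_bound": 0},
    {"id": "EX_glcb_e", "metabolites": {"glcb_e": -1}, "lower_bound": -2, "upper_bound": 0},
    {"id": "EX_asp_e", "metabolites": {"asp_e": -1}, "lower_bound": -5, "upper_bound": 0},
    {"id": "EX_gln_e", "metabolites": {"gln_e": -1}, "lower_bound": -3, "upper_bound": 0},
    {"id": "CAT_NACGAM", "metabolites": {"nacgam_e": -1, "f6p": 1}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "CAT_GLCA", "metabolites": {"glca_e": -1, "f6p": 1}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "CAT_GLCB", "metabolites": {"glcb_e": -1, "f6p": 1}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "CAT_ASP", "metabolites": {"asp_e": -1, "oaa": 1}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "CAT_GLN", "metabolites": {"gln_e": -1, "oaa": 1}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "BIOMASS", "metabolites": {"f6p": -1, "oaa": -0.4}, "lower_bound": 0, "upper_bound": 9.5, "objective_coefficient": 1}
  ]
}
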