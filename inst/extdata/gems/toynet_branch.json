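{
  "id": "toynet_branch",
  "description": "Branched toy network: one substrate (max uptake 10) splits into two precursors that the biomass reaction consumes 1:1, so the optimum is the stoichiometric split 5.",
  "metabolites": [
    {"id": "A"},
    {"id": "B"},
    {"id": "C"}
  ],
  "reactions": [
    {"id": "EX_A", "metabolites": {"A": -1}, "lower_bound": -10, "upper_bound": 0},
    {"id": "R_AB", "metabolites": {"A": -1, "B": 1}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "R_AC", "metabolites": {"A": -1, "C": 1}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "BIOMASS", "metabolites": {"B": -1, "C": -1}, "lower_bound": 0, "upper_bound": 1000, "objective_coefficient": 1}
  ]
}
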