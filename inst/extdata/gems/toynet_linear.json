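{
  "id": "toynet_linear",
  "description": "Minimal linear chain: substrate uptake (max 10) feeds a 1:1 conversion into the biomass precursor; the optimum equals the uptake bottleneck.",
  "metabolites": [
    {"id": "A"},
    {"id": "B"}
  ],
  "reactions": [
    {"id": "EX_A", "metabolites": {"A": -1}, "lower_bound": -10, "upper_bound": 0},
    {"id": "R_AB", "metabolites": {"A": -1, "B": 1}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "BIOMASS", "metabolites": {"B": -1}, "lower_bound": 0, "upper_bound": 1000, "objective_coefficient": 1}
  ]
}
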