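# Mucin-degrader monoculture: single-phase growth on mucin O-glycans.
# The slowest of the three strains to adapt over serial passages
# (largest initial lag excess).
scenario: monoculture_am
strains:
  - name: A_muciniphila
    copy_number: 3
    lag_h: 2.0
    heat_yield_J_per_gDW: 1500
    mu_max: {am_glycans: 0.57}
    K: {am_glycans: 0.001}
    yield_X: {am_glycans: 0.02}
    yield_P:
      acetate: {am_glycans: 1.0}
      propionate: {am_glycans: 0.6}
medium:
  am_glycans: 17.0
  acetate: 1.0
initial_biomass:
  A_muciniphila: 0.0025
transfer_fraction: 0.01
volume_L: 0.002
passages: 7
duration_h: 24
dt_h: 0.02
replicates: 3
adaptation:
  lag_excess: 0.0625
  mu_deficit: 0.05
  factor: 0.1
lag_jitter_sd_h: 0.00107
instrument_tau_h: 0.05
measurement_noise_W: 0.0
metabolite_noise_mM: 0.3
read_depth: 100000
abundance_interval_h: 1.0
pca_grid: {from: 0.5, to: 23.5, by: 0.1}
truth:
  stability_passage: 4
  phases:
    A_muciniphila: {mu: [0.57], sd: [0.02]}
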