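# Generalist monoculture: three growth phases from sequential depletion
# of mucin O-glycans, peptides and slowly degraded mucin core.  The
# per-substrate maxima (0.88, 0.13, 0.07) give observed phase rates
# 0.88, 0.20 and 0.07 1/h under the additive capped Monod law.
scenario: monoculture_bt
strains:
  - name: B_thetaiotaomicron
    copy_number: 5
    lag_h: 1.5
    heat_yield_J_per_gDW: 1500
    mu_max: {bt_glycans: 0.88, bt_peptides: 0.13, bt_mucin_core: 0.07}
    K: {bt_glycans: 0.001, bt_peptides: 0.001, bt_mucin_core: 0.001}
    yield_X: {bt_glycans: 0.02, bt_peptides: 0.02, bt_mucin_core: 0.02}
    yield_P:
      acetate: {bt_glycans: 1.2, bt_peptides: 1.2}
      propionate: {bt_glycans: 0.5}
      succinate: {bt_glycans: 0.3}
medium:
  bt_glycans: 10.0
  bt_peptides: 7.0
  bt_mucin_core: 9.0
  acetate: 1.0
initial_biomass:
  B_thetaiotaomicron: 0.0025
transfer_fraction: 0.01
volume_L: 0.002
passages: 7
duration_h: 24
dt_h: 0.02
replicates: 3
adaptation:
  lag_excess: 0.05
  mu_deficit: 0.05
  factor: 0.1
lag_jitter_sd_h: 0.126
instrument_tau_h: 0.05
measurement_noise_W: 0.0
metabolite_noise_mM: 0.3
read_depth: 100000
abundance_interval_h: 1.0
pca_grid: {from: 0.5, to: 23.5, by: 0.1}
truth:
  stability_passage: 2
  phases:
    B_thetaiotaomicron: {mu: [0.88, 0.20, 0.07], sd: [0.06, 0.01, 0.002]}
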