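# Three-strain gut consortium in a mucin-supplemented rich medium.
# Substrate pools are strain-specific niches (mucin O-glycans, peptides,
# slowly degraded mucin core for the generalist); acetate is cross-fed
# from the two acetate producers to the butyrate producer through a
# non-growth-associated conversion.  Per-substrate maximum rates are
# chosen so that the additive capped Monod law reproduces the measured
# phase-specific growth rates (see truth block).
scenario: consortium
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
  - name: F_prausnitzii
    copy_number: 6
    lag_h: 1.5
    heat_yield_J_per_gDW: 1500
    mu_max: {fp_sugars: 1.00, fp_peptides: 0.12, fp_acids: 0.09}
    K: {fp_sugars: 0.001, fp_peptides: 0.001, fp_acids: 0.001}
    yield_X: {fp_sugars: 0.02, fp_peptides: 0.02, fp_acids: 0.02}
    yield_P:
      butyrate: {fp_sugars: 0.6, fp_peptides: 0.6}
      formate: {fp_sugars: 0.8}
    conversion:
      substrate: acetate
      product: butyrate
      v_max: 2.5
      K: 0.5
      yield: 1.0
medium:  # mmol/L
  am_glycans: 17.0
  bt_glycans: 10.0
  bt_peptides: 7.0
  bt_mucin_core: 9.0
  fp_sugars: 2.0
  fp_peptides: 1.65
  fp_acids: 2.75
  acetate: 1.0
initial_biomass:  # gDW/L
  A_muciniphila: 0.0025
  B_thetaiotaomicron: 0.0025
  F_prausnitzii: 0.0025
transfer_fraction: 0.01
volume_L: 0.002
passages: 7
duration_h: 24
dt_h: 0.02
replicates: 3
adaptation:
  lag_excess: 0.13
  mu_deficit: 0.05
  factor: 0.1
lag_jitter_sd_h: 0.0119
instrument_tau_h: 0.05
measurement_noise_W: 0.0
metabolite_noise_mM: 0.3
read_depth: 100000
abundance_interval_h: 1.0
pca_grid: {from: 0.5, to: 23.5, by: 0.1}
truth:
  stability_passage: 3
  composition:
    A_muciniphila: 0.343
    B_thetaiotaomicron: 0.525
    F_prausnitzii: 0.131
  phases:
    A_muciniphila: {mu: [0.57], sd: [0.02]}
    B_thetaiotaomicron: {mu: [0.88, 0.20, 0.07], sd: [0.06, 0.01, 0.002]}
    F_prausnitzii: {mu: [1.00, 0.21, 0.09], sd: [0.08, 0.01, 0.004]}
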