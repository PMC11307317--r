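# Butyrate-producer monoculture: three growth phases on sugars, peptides
# and residual organic acids; cannot use mucin-derived monosaccharides.
# Limited butyrate formation from the small amount of acetate present in
# the fresh medium.
scenario: monoculture_fp
strains:
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
medium:
  fp_sugars: 2.0
  fp_peptides: 1.65
  fp_acids: 2.75
  acetate: 1.0
initial_biomass:
  F_prausnitzii: 0.0025
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
lag_jitter_sd_h: 0.0469
instrument_tau_h: 0.05
measurement_noise_W: 0.0
metabolite_noise_mM: 0.3
read_depth: 100000
abundance_interval_h: 1.0
pca_grid: {from: 0.5, to: 23.5, by: 0.1}
truth:
  stability_passage: 2
  phases:
    F_prausnitzii: {mu: [1.00, 0.21, 0.09], sd: [0.08, 0.01, 0.004]}
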