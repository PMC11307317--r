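# calorimix

Analysis of defined anaerobic gut bacterial consortia monitored by
isothermal microcalorimetry (IMC) over serial passages — built around a
three-strain community of the mucin specialist *Akkermansia muciniphila*,
the generalist *Bacteroides thetaiotaomicron* and the butyrate producer
*Faecalibacterium prausnitzii*, the kind of next-generation-probiotic
consortium studied by continuous calorimetric monitoring.

The package is for microbial physiologists and microbiome engineers who
grow defined communities in sealed IMC ampoules and need to turn
heat-flow thermograms, 16S read counts and endpoint metabolite panels
into growth rates, stability/resilience calls and metabolic constraints.

## What it computes

* **Calorimetric growth kinetics.** Under growth-associated heat release
  the heat flow of strain *i* is `P_i = Y_Q dX_i/dt·V`, so cumulative heat
  is proportional to biomass and the specific growth rate μ is the slope
  of ln(heat flow) against time. Polyphasic thermograms are segmented by
  exact dynamic-programming changepoint regression of ln P(t), with the
  number of phases chosen by BIC — each segment slope is a
  phase-specific μ (h⁻¹).
* **Composition.** 16S read counts are normalized by rRNA gene copy
  number (`fraction_i ∝ reads_i / c_i`, copies 3/5/6 for the three
  strains), and consortium heat is deconvolved into per-strain growth
  curves as `Q_i(t) = Q_total(t)·a_i(t)` with abundances `a_i`
  interpolated onto the heat grid.
* **Stability and resilience.** Heat-flow curves across passages are
  compared by PCA; the consortium is stable from the first passage whose
  subsequent centroid shifts all stay within `k·d_w` of each other
  (`d_w` = within-passage replicate dispersion), and a perturbed
  (100-fold under-inoculated) community has recovered when its passage
  centroid re-enters the reference stable region.
* **Metabolite exchange.** Endpoint concentration changes are compared
  between the consortium and the replicate-wise *stack* of monocultures
  (Student's t-test with significance stars), and converted to exchange
  rates `q = ΔC/X·μ` (mmol·gDW⁻¹·h⁻¹) for constraint-based modeling.
* **Flux balance analysis.** An in-package simplex LP core solves FBA,
  flux variability analysis, random-objective flux sampling and
  substrate-depletion screens (essential / limiting / dispensable) on
  genome-scale models read from JSON or SBML-fbc.
* **A consortium simulator** (multi-strain capped-additive Monod growth,
  growth-associated heat with a first-order instrument response, 1% v/v
  serial passaging with adaptation drift, multinomial read sampling,
  endpoint metabolite noise) generates every input type with designed
  ground truths; packaged scenarios encode the study conditions.

## Worked example

```r
library(calorimix)

# Simulate the generalist monoculture over 7 passages and estimate its
# phase-specific growth rates from a late, stable passage.
fx   <- load_fixture("monoculture_bt")
sims <- simulate_serial_passages(fx$params, n_passages = 5,
                                 instrument_tau = 0.05, seed = 1)
s  <- sim_heatflow_series(sims[[5]])
segment_phases(s, max_phases = 3)
#> <growth_phase> 3 phase(s)
#>  t_start t_end      mu fit_r2 n_points
#>     1.64  5.96 0.88000      1      171
#>     5.98  8.54 0.19950      1      101
#>     8.56 11.66 0.06958      1      123
```

Three growth phases, fastest first: the strain grows at 0.88 h⁻¹ on its
preferred substrate, then at 0.20 h⁻¹ and finally 0.07 h⁻¹ as successive
substrate pools deplete — the phase rates this scenario was designed
around. `fit_r2` is the per-phase log-linear fit quality and `n_points`
the points retained after edge trimming.

A full pipeline run (fixture generation, kinetics, stability, composition,
resilience, metabolites, FBA) is one call:

```r
manifest <- run_pipeline(run_config(list(seed = 1, outdir = "run1")))
```

or from the shell via the thin CLI:

```sh
Rscript inst/scripts/calorimix run --config run.yaml
Rscript inst/scripts/calorimix fixtures --scenario consortium --seed 1 --outdir data
```

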