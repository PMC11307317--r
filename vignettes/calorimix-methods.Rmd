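---
title: "Models and methods behind calorimix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind calorimix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

calorimix analyzes defined anaerobic gut bacterial consortia monitored by
isothermal microcalorimetry (IMC) over serial 1% (v/v) passages, together
with 16S rRNA amplicon composition, endpoint metabolite panels and
constraint-based metabolic models. This vignette explains the models the
package implements, the choices behind their defaults, and what the
packaged synthetic scenarios do and do not establish.

## The measurement model

An IMC channel reports the heat flow (W) of a sealed 2 mL ampoule. Under
anaerobic batch growth the package assumes heat release is purely
growth-associated: strain $i$ releases

$$P_i(t) = Y_{Q,i}\,\frac{dX_i}{dt}\,V,$$

with $Y_{Q,i}$ the heat yield per gram dry weight of new biomass (J/gDW),
$X_i$ the biomass concentration (gDW/L) and $V$ the working volume. The
cumulative heat is then exactly proportional to the biomass increment,
$Q_i(t) = Y_{Q,i}(X_i(t)-X_i(0))V$ — the linearity between heat and
biomass that underpins calorimetric growth-rate estimation. No maintenance
term is included by default: with a maintenance term the heat–biomass
relationship would acquire a time-dependent offset, which the data this
package emulates do not show. During exponential growth both the heat flow
and (asymptotically) the total heat grow as $e^{\mu t}$, so the specific
growth rate is a log-slope.

Heat yields per strain are not experimentally pinned for these organisms;
the simulator uses one configurable value per strain with a shared default
of 1500 J/gDW, which puts a 2 mL culture reaching ~0.5 gDW/L at a total
heat of ~1.5 J and peak heat flows of one to two hundred microwatts,
typical magnitudes for anaerobic gut isolates in IMC.

The simulator also models the *instrument*: a thermopile senses heat
through a first-order thermal response, so the measured signal is the
metabolic heat flow filtered with a time constant `instrument_tau_h`
(default 0.05 h, i.e. a ~3 min thermopile). The filter is co-integrated
inside the ODE, not applied to sampled output, so the measured curves are
exact and free of sampling aliasing. A pure exponential phase passes
through the filter with its log-slope unchanged (only its amplitude is
scaled by $1/(1+\mu\tau)$), so growth-rate estimation is unaffected;
sub-minute features such as the sharp heat-flow drop at substrate
depletion are smeared over $\tau$, as in real thermograms.

## Community growth kinetics

Growth is multi-substrate Monod with additive terms capped at the best
single-substrate rate:

$$\mu_i(S) = \min\Big(\sum_k \mu^{max}_{ik}\,\frac{S_k}{K_{ik}+S_k},\;
\max_k \mu^{max}_{ik}\Big).$$

The cap prevents unbounded stacking of parallel pathways. Substrate
consumption is partitioned across substrates in proportion to their
contribution to $\mu_i$, divided by the biomass yield $Y^X_{ik}$; products
follow fixed yields $Y^P$ (mmol product per mmol substrate). A lag phase
precedes growth; to keep trajectories continuous in the lag parameter the
activation rises linearly over a short ramp (0.05 h) rather than switching
discontinuously.

One deliberate extension is a *non-growth-associated conversion*: a strain
may convert one external compound to another at rate
$v_{max}\,S/(K+S)\,X$ without biomass or heat coupling. This models
CoA-transferase-style cross-feeding — acetate produced by the two
mucin degraders is converted to butyrate by the butyrate producer — while
leaving the producer's growth phases at their monoculture values. The
packaged consortium roughly doubles its butyrate relative to the
butyrate-producer monoculture through this route.

The ODE system is integrated with an adaptive implicit solver
(`deSolve::ode(method = "lsode")`, rtol $10^{-8}$, atol $10^{-12}$),
split at the lag ramp edges so the solver never steps across a kink.
Substrate depletion with half-saturation constants of $10^{-3}$ mmol/L is
stiff; the BDF-capable lsode integrates it reliably where the default
Adams/BDF switching heuristic fails.

Serial passaging transfers 1% (v/v) of the culture into fresh medium:
the next inoculum is `transfer_fraction` times the end-of-passage biomass,
and the transferred liquid carries the same fraction of the spent compound
pool. Passage-dependent adaptation moves lag times (and optionally
maximum rates) geometrically towards their asymptotes with a per-passage
factor $r$; replicate ampoules additionally receive a small uniform lag
jitter representing inoculum-physiology variability.

## Growth-rate estimation and phase segmentation

`estimate_growth_rate()` regresses $\ln$(heat flow) on time. The
alternative `"heat-log"` method regresses $\ln$(total heat), the quantity
classically quoted for IMC; it converges to the same slope once
$e^{\mu t} \gg 1$ but is biased upward early in a phase, which the
documentation and tests make explicit. The default uses the heat flow
because it is exact for exponential growth at all times.

Polyphasic thermograms are segmented by exact dynamic programming over
changepoints of a piecewise linear model of $\ln P(t)$: for every
candidate phase count up to `max_phases` the globally optimal segmentation
is computed (ties broken towards the earliest breakpoint), and BIC with a
penalty of $\ln n$ per parameter (each segment's slope and intercept and
each breakpoint count) selects the count. Numerical choices:

* the log signal is smoothed with a centered moving median (width 5) to
  suppress isolated spikes;
* points below the noise floor (3x the baseline-window standard deviation
  when available, otherwise non-positive values) are excluded, and the
  series is truncated after the last point above 5% of the peak power;
* leading and trailing runs of extreme local log-slope are trimmed
  (above +3 1/h at the head, below -1 1/h at the tail): the lag-release
  and instrument warm-up rise far faster than any growth phase, and the
  terminal starvation collapse falls far faster, so neither is phase
  signal;
* a small variance floor ($10^{-6}$ of the log-range, squared) enters the
  BIC likelihood so that numerically exact fits on noiseless data do not
  degenerate;
* segments shorter than `min_duration` (1 h) are merged into whichever
  neighbour increases the error least; adjacent segments whose slopes
  differ by less than 5% are merged, since a genuine metabolic phase
  change implies a distinct rate;
* each phase's rate is re-estimated by OLS after trimming 10% of the
  points at each segment edge (where Monod transitions bend the log
  signal) and one MAD-based outlier-rejection pass.

With these defaults the packaged monoculture scenarios recover their
designed phase structure to well within the reported uncertainties
(single 0.57 1/h phase for the mucin specialist; 0.88/0.20/0.07 and
1.00/0.21/0.09 1/h for the two polyphasic strains) from the late, stable
passages (5–7).

The per-substrate maxima behind a polyphasic fixture are chosen so the
additive capped law reproduces the observed phase rates: a strain with
per-substrate maxima (0.88, 0.13, 0.07) grows at 0.88 (capped) while the
preferred substrate lasts, at 0.13 + 0.07 = 0.20 after its depletion, and
at 0.07 in the final phase.

## Composition and heat deconvolution

Amplicon read counts scale with biomass and with 16S rRNA gene copy
number (3, 5 and 6 copies for the three strains), so normalization divides
reads by copies before computing fractions. The simulator inverts this as
a forward model: reads are multinomial with probabilities proportional to
biomass fraction times copy number.

Consortium heat is deconvolved by partitioning the cumulative heat among
strains in proportion to (optionally heat-yield-weighted) abundance.
Equal heat yield per gDW across strains is the default, which is the
implicit assumption when partitioning heat by abundance alone; per-strain
weights are exposed for sensitivity analysis. Abundances sampled hourly
are interpolated linearly in fraction space and renormalized to the
simplex (linear interpolation can leave the simplex; renormalization
restores it). Whether to interpolate or step between samples is not
dictated by the data; linear interpolation is this package's choice.
The deconvolved per-strain heats sum to the total exactly at every grid
point by construction.

## Stability and resilience

Stability means reproducibility of heat-flow curves between consecutive
passages. Curves are resampled to a common grid, stacked into a
(passage x replicate) by time matrix and decomposed by PCA. Two
conventions differ here deliberately:

* `pca_scores()` defaults to centered **and scaled** data — the
  convention for heterogeneous variable panels such as the amino-acid
  profiles;
* the stability detector runs on centered, **unscaled** heat-flow PCA.
  Heat-flow columns share one physical unit, and unit-variance scaling
  would give flat baseline columns (pure noise) the same weight as signal
  columns, distorting between-passage distances.

In the leading two-PC plane, the pooled mean replicate-to-centroid
distance $d_w$ measures replicate noise, and the stability passage is the
first passage from which every subsequent consecutive-passage centroid
shift stays within $k\,d_w$. The default $k = 4$ comes from a power
analysis: with triplicate ampoules the standard error of a difference of
two passage centroids is about $1.25\,d_w$, so thresholds below ~$3 d_w$
are crossed by pure replicate noise at a rate of several percent per
passage pair, producing false "instability" flags; $k = 4$ puts the
threshold about three standard errors above the noise floor while
remaining far below genuine between-passage drift. The criterion is
monotone in $k$ by construction.

Resilience projects the curves of a perturbed run (one strain inoculated
100-fold lower) into the reference PCA; the recovery passage is the first
whose centroid falls within $k\,d_w$ of the reference stable-region
centroid. Unlike the stability criterion, this comparison is made in the
full retained score space of the reference decomposition (the pipeline
retains 10 components), with $d_w$ recomputed in the same space: in two
dimensions the apparent magnitude of the perturbation residual depends on
how replicate noise happens to rotate the leading axes, whereas
higher-dimensional distances are rotation-proof. A subtlety worth knowing:
even after the under-inoculated strain has caught up, its run carries a
small deterministic "memory" into the next passage (inoculum and
carry-over differences of order one percent), so the detection threshold
must sit above that residual — the packaged scenarios are constructed
accordingly. Composition recovery is assessed separately as the first
passage whose copy-number-normalized composition is within a tolerance
(default 5 percentage points, 2 in the validation suite) of the reference.

The stability scenarios are built to their designed passage counts: the
adaptation drift decays geometrically (factor 0.1 per passage for the
stability suite), the drift amplitudes stay in the regime where curve
distance responds linearly to lag offsets (passage-1 offsets of at most
~0.5 h), and the replicate jitter is set so that the detection threshold
$k\,d_w$ falls midway between the consecutive-passage shifts at the
designed stability passage and the one before it. The resilience
scenarios reuse the consortium with a 100-fold under-inoculation of one
strain plus a re-adaptation schedule of the diluted strain whose kinetic
offset crosses the reference threshold at the designed recovery passage
(passage 5 for the slow-adapting mucin specialist, 2 for the other two).
Because each strain occupies its own substrate niche and batches reach
substrate exhaustion well before transfer, the end-of-passage composition
self-corrects within about two passages regardless of the perturbation —
the designed kinetic recovery is carried by the re-adaptation schedule.

## Metabolite exchange

Endpoint concentration changes (end − start, mmol/L) are summarized per
replicate. The "no interaction" expectation for the consortium is the
stack of the monoculture changes; stacking is done per replicate index
(replicate r of the stack is the sum of the strains' replicate-r deltas)
rather than on means, which reproduces the stacked means exactly while
retaining replicate variance for the test. Consortium and stacked
replicates are compared with a two-sided equal-variance Student's t-test
(the laterality is not dictated; two-sided is the conservative choice),
starred at p < 0.05/0.01/0.001. No multiple-testing correction is applied
by default, matching how such panels are conventionally reported;
Benjamini–Hochberg adjustment is available behind a flag. Zero-variance
degenerate comparisons are handled explicitly: identical groups give
t = 0, p = 1; constant but different groups are flagged with p reported
as 0.

Concentration changes become exchange-rate constraints as
$q = (\Delta C / X)\,\mu$ (mmol/gDW/h), assuming the changes accumulated
before stationary phase. The biomass denominator may come from an OD
conversion (default 0.4 gDW/L per OD600 unit — a configurable convention,
not a measured value).

## Constraint-based analysis

A genome-scale model is a stoichiometric matrix with flux bounds and a
biomass objective; exchange reactions are single-metabolite boundary
reactions with uptake negative (the standard fbc sign convention). FBA
maximizes the objective by linear programming over
$\{S v = 0,\ lb \le v \le ub\}$. The LP solver is a dense two-phase
primal simplex with Bland's anti-cycling rule implemented in the package;
on every release it is cross-checked against a brute-force
vertex-enumeration oracle on dozens of random bounded networks. Because
optimal vertices are degenerate in general, assertions target objective
values, FVA intervals or sampled statistics, never a particular vertex.

Measured exchange rates constrain the model as windows
$[q - sd,\ q + sd]$ clipped into the model's feasible orientation; a rate
of zero with zero sd fixes the exchange (depletion semantics). The
depletion screen sets each substrate's uptake bound to zero, re-solves,
and classifies the substrate as essential (objective below $10^{-6}$),
limiting (below 95% of the reference optimum — the reference analysis
reports a "significant decrease" without a number, so a threshold had to
be chosen), or dispensable. FVA computes per-reaction flux ranges at a
fraction of the optimum (the conventional setting is 90%); flux sampling
solves LPs with random unit-sphere objectives inside the near-optimal
polytope and reports per-reaction means and standard deviations, which is
how "n = 5000 samples" summaries of near-optimal flux distributions are
produced.

The curated genome-scale models behind the original analysis are not
available in pinned form, so absolute flux predictions are out of reach.
The package ships small synthetic toy networks (labelled `_synthetic`)
expressing the qualitative essentiality patterns instead: the mucin
specialist with N-acetylglucosamine, asparagine and threonine each
individually essential; the generalist with a wide substrate range, no
essential single substrate and only aspartate/N-acetylglucosamine
limiting; the butyrate producer with serine, threonine and uracil
essential and acetate uptake dispensable for growth but convertible to
butyrate.

## Problem sizes and what the tests show

The packaged scenarios use 7 passages x 3 replicates, 24 h batches on a
0.02 h grid, hourly abundance sampling at 1e5 reads, and metabolite
panels with 0.3 mmol/L measurement noise — matching the scale of the
experimental design they emulate. The validation suite runs the full
pipeline on these scenarios and checks parameter recovery against the
designed truths.

Passing these tests shows that the estimators recover known truths under
the simulator's assumptions: growth-associated heat, strain-specific
substrate niches, multiplicative adaptation drift, multinomial read
sampling, Gaussian endpoint noise. Real data violate some of these in
ways the simulator does not emulate — maintenance heat, pH drift and
endothermic events, chimeric or misassigned reads, shared-substrate
competition, day effects between passages — so recovery here bounds
estimator correctness, not real-world accuracy.

## Known limitations

* Heat is strictly growth-associated; endothermic processes and
  maintenance metabolism are not modelled (an optional maintenance term is
  deliberately absent rather than silently defaulted).
* The stability criterion quantifies what the original analysis judged
  visually; passage counts depend on $k$, and the packaged fixtures are
  validated against this package's criterion, not against an independent
  statistical definition of stability.
* Mucin-glycan cleavage chemistry, pH dynamics and gas-phase effects are
  out of scope; mucin consumption enters only as monosaccharide pools.
* The toy metabolic networks are qualitative stand-ins; no quantitative
  flux value from them should be compared to a curated model.
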