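## Multi-strain Monod batch simulator with growth-associated heat release.
##
## Growth law: after its lag, strain i grows at
##   mu_i(S) = min( sum_k mu_max_ik * S_k / (K_ik + S_k), max_k mu_max_ik )
## (additive Monod terms capped at the best single-substrate rate, so
## parallel substrates cannot stack beyond the fastest pathway).  Substrate
## consumption is partitioned over substrates in proportion to their
## contribution to mu_i; products follow through fixed yields; heat flow is
## purely growth-associated, P_i = Y_Q,i * dX_i/dt (no maintenance term).

## Assemble the compound universe and dense kinetic matrices once per call.
build_sim_structure <- function(params) {
  strains <- params$strains
  sn <- names(strains)
  compounds <- names(params$substrates)
  for (st in strains) {
    compounds <- union(compounds, names(st$mu_max))
    if (!is.null(st$yield_P)) compounds <- union(compounds, names(st$yield_P))
    if (!is.null(st$conversion))
      compounds <- union(compounds, c(st$conversion$substrate, st$conversion$product))
  }
  nS <- length(strains); nC <- length(compounds)
  MU <- KM <- YX <- matrix(0, nS, nC, dimnames = list(sn, compounds))
  KM[] <- 1  # placeholder for unused entries, never touched when MU == 0
  YP <- vector("list", nS); names(YP) <- sn
  conv <- vector("list", nS); names(conv) <- sn
  for (i in seq_len(nS)) {
    st <- strains[[i]]
    MU[i, names(st$mu_max)] <- st$mu_max
    KM[i, names(st$K)] <- st$K
    YX[i, names(st$yield_X)] <- st$yield_X
    if (!is.null(st$yield_P)) {
      m <- matrix(0, nC, nC, dimnames = list(compounds, compounds))
      for (prod in names(st$yield_P)) {
        v <- st$yield_P[[prod]]
        m[prod, names(v)] <- v
      }
      YP[[i]] <- m
    }
    if (!is.null(st$conversion)) {
      cv <- st$conversion
      conv[[i]] <- list(s = match(cv$substrate, compounds),
                        p = match(cv$product, compounds),
                        v_max = cv$v_max, K = cv$K, yield = cv$yield)
    }
  }
  list(strain_names = sn, compounds = compounds, nS = nS, nC = nC,
       MU = MU, KM = KM, YX = YX, YP = YP, conv = conv,
       cap = apply(MU, 1, max),
       heat_yield = vapply(strains, `[[`, 0, "heat_yield"),
       lag = vapply(strains, `[[`, 0, "lag_h"))
}

## Instantaneous rates at state (X, C).  `act` is the per-strain lag
## activation in [0, 1]: growth switches on along a short linear ramp
## after the lag so that trajectories respond continuously to lag
## parameters.  Returns mu (h^-1 per strain), compound derivative
## (mmol/L/h) and biomass derivative (gDW/L/h).
sim_rates <- function(str, X, C, act) {
  Cm <- matrix(C, str$nS, str$nC, byrow = TRUE)
  term <- str$MU * Cm / (str$KM + Cm)
  g <- rowSums(term)
  mu <- pmin(g, str$cap) * act
  scale <- ifelse(g > 0, mu / g, 0)
  cons <- (term / str$YX) * (scale * X)      # mmol/L/h consumed, strain x compound
  cons[!is.finite(cons)] <- 0
  dC <- -colSums(cons)
  for (i in seq_len(str$nS)) {
    if (!is.null(str$YP[[i]]))
      dC <- dC + as.numeric(str$YP[[i]] %*% cons[i, ])
    cv <- str$conv[[i]]
    if (!is.null(cv) && act[i] > 0) {
      rate <- cv$v_max * C[cv$s] / (cv$K + C[cv$s]) * X[i] * act[i]
      dC[cv$s] <- dC[cv$s] - rate
      dC[cv$p] <- dC[cv$p] + cv$yield * rate
    }
  }
  list(mu = mu, dX = mu * X, dC = dC)
}

lag_activation <- function(t, lag, ramp) {
  if (ramp <= 0) return(as.numeric(t >= lag - 1e-12))
  pmin(1, pmax(0, (t - lag) / ramp))
}

#' Simulate one batch fermentation of a consortium
#'
#' Integrates the community growth ODE on a regular time grid and returns
#' biomass, compound and heat trajectories. Heat release is
#' growth-associated: the heat flow of strain i is
#' `heat_yield_i * dX_i/dt * volume` and its cumulative heat is exactly
#' proportional to the biomass it has formed.
#'
#' @param params A [community_params()] object.
#' @param duration Batch duration (h).
#' @param dt Output grid spacing (h).
#' @param seed Unused (the batch ODE is deterministic); accepted so that
#'   all simulator entry points share a signature.
#' @param lag_shift Optional named vector of additive lag offsets (h) per
#'   strain, used by the serial-passage driver for adaptation drift and
#'   replicate jitter.
#' @param mu_scale Optional named vector of multiplicative growth-rate
#'   factors per strain.
#' @param initial_biomass,substrates Optional overrides of the inoculum
#'   and medium in `params`.
#' @param lag_ramp Duration (h) of the linear activation ramp ending the
#'   lag phase; keeps trajectories continuous in the lag parameters.
#' @param instrument_tau Thermopile time constant (h). When positive, the
#'   measured heat flow is co-integrated as a first-order response to the
#'   metabolic heat flow, exactly as a calorimeter senses it; the result
#'   carries both the instantaneous (`heat_flow`) and measured
#'   (`heat_flow_meas`) signals.
#' @param rtol Relative tolerance of the adaptive ODE solver.
#'
#' @return An object of class `consortium_sim`: list with `time` (h),
#'   `biomass` (gDW/L, time x strain), `compounds` (mmol/L),
#'   `growth_rate` (h^-1), `heat_flow` (W per ampoule, per strain),
#'   `heat_flow_total`, `cum_heat` (J per ampoule) and `cum_heat_total`.
#' @export
simulate_batch <- function(params, duration = 24, dt = 0.02, seed = NULL,
                           lag_shift = NULL, mu_scale = NULL,
                           initial_biomass = NULL, substrates = NULL,
                           lag_ramp = 0.05, instrument_tau = 0, rtol = 1e-8) {
  stopifnot(inherits(params, "community_params"))
  if (!is_scalar_num(duration) || duration <= 0) stop_bad_arg("duration must be > 0")
  if (!is_scalar_num(dt) || dt <= 0) stop_bad_arg("dt must be > 0")
  str <- build_sim_structure(params)
  lag <- str$lag + named_or(lag_shift, str$strain_names, 0)
  if (!is.null(mu_scale)) {
    sc <- named_or(mu_scale, str$strain_names, 1)
    str$MU <- str$MU * sc
    str$cap <- str$cap * sc
  }
  X0 <- if (is.null(initial_biomass)) params$initial_biomass else
    named_or(initial_biomass, str$strain_names, 0)
  C0 <- named_or(if (is.null(substrates)) params$substrates else substrates,
                 str$compounds, 0)
  times <- seq(0, duration, by = dt)
  if (abs(times[length(times)] - duration) > 1e-9) times <- c(times, duration)

  V <- params$volume_L
  nXC <- str$nS + str$nC
  deriv <- function(t, y, p) {
    X <- y[seq_len(str$nS)]
    C <- pmax(y[(str$nS + 1):nXC], 0)
    r <- sim_rates(str, X, C, act = lag_activation(t, lag, lag_ramp))
    if (instrument_tau > 0) {
      P <- str$heat_yield * r$dX * V / 3600
      dM <- (P - y[(nXC + 1):(nXC + str$nS)]) / instrument_tau
      return(list(c(r$dX, r$dC, dM)))
    }
    list(c(r$dX, r$dC))
  }
  ## integrate piecewise between lag switch times so the solver never steps
  ## across a derivative kink
  switches <- sort(unique(c(lag, lag + lag_ramp)))
  switches <- switches[switches > 0 & switches < duration]
  edges <- unique(c(0, switches, duration))
  y <- c(X0, C0)
  if (instrument_tau > 0) y <- c(y, rep(0, str$nS))
  out <- matrix(NA_real_, length(times), length(y))
  out[1, ] <- y
  for (e in seq_len(length(edges) - 1L)) {
    seg <- times[times >= edges[e] - 1e-12 & times <= edges[e + 1] + 1e-12]
    seg <- sort(unique(c(edges[e], seg, edges[e + 1])))
    seg <- seg[c(TRUE, diff(seg) > 1e-9)]
    sol <- deSolve::ode(y, seg, deriv, parms = NULL, method = "lsode",
                        rtol = rtol, atol = 1e-12, maxsteps = 100000)
    if (any(!is.finite(sol))) {
      bad <- sol[, 1][which(!is.finite(rowSums(sol)))[1]]
      stop("ODE integration produced a non-finite state at t = ",
           signif(bad, 6), " h", call. = FALSE)
    }
    keep <- match(round(times, 10), round(sol[, 1], 10))
    ok <- !is.na(keep)
    out[ok, ] <- sol[keep[ok], -1, drop = FALSE]
    y <- sol[nrow(sol), -1]
  }
  biomass <- out[, seq_len(str$nS), drop = FALSE]
  compounds <- out[, (str$nS + 1):nXC, drop = FALSE]
  colnames(biomass) <- str$strain_names
  colnames(compounds) <- str$compounds
  heat_flow_meas <- NULL
  if (instrument_tau > 0) {
    heat_flow_meas <- out[, (nXC + 1):(nXC + str$nS), drop = FALSE]
    colnames(heat_flow_meas) <- str$strain_names
  }
  ## exact growth rates on the grid (recomputed from the state, not by
  ## finite differences)
  mu <- t(vapply(seq_along(times), function(j) {
    sim_rates(str, biomass[j, ], pmax(compounds[j, ], 0),
              act = lag_activation(times[j], lag, lag_ramp))$mu
  }, numeric(str$nS)))
  mu <- matrix(mu, ncol = str$nS, dimnames = list(NULL, str$strain_names))
  heat_flow <- sweep(mu * biomass, 2, str$heat_yield, `*`) * V / 3600
  cum_heat <- sweep(sweep(biomass, 2, biomass[1, ], `-`), 2,
                    str$heat_yield, `*`) * V
  structure(list(time = times, biomass = biomass, compounds = compounds,
                 growth_rate = mu, heat_flow = heat_flow,
                 heat_flow_total = rowSums(heat_flow),
                 heat_flow_meas = heat_flow_meas,
                 heat_flow_meas_total = if (is.null(heat_flow_meas)) NULL
                 else rowSums(heat_flow_meas),
                 cum_heat = cum_heat, cum_heat_total = rowSums(cum_heat),
                 passage = 1L, params = params),
            class = "consortium_sim")
}

#' Simulate serial passages of a consortium
#'
#' Runs `n_passages` sequential batches. Each new passage is inoculated
#' with `transfer_fraction` of the end-of-passage biomass into fresh
#' medium (the transferred liquid also carries over the same fraction of
#' the spent compound pool). Optional adaptation drift moves lag times and
#' growth rates geometrically towards their asymptotic values, and
#' `per_strain_dilution` perturbs the first inoculum only, mimicking
#' under-inoculation resilience experiments.
#'
#' @inheritParams simulate_batch
#' @param n_passages Number of passages (>= 1).
#' @param per_strain_dilution Named or unnamed vector of multiplicative
#'   factors applied to the passage-1 inoculum only (default 1 for all
#'   strains; 0.01 means a 100-fold under-inoculation).
#' @param lag_jitter_sd Standard deviation (h) of uniform replicate lag
#'   jitter, drawn independently per strain and passage; models
#'   inoculum-physiology variability between replicate ampoules.
#' @param seed Seed for the jitter draws.
#'
#' @return List of `consortium_sim` objects, one per passage, each with its
#'   `passage` element set.
#' @export
simulate_serial_passages <- function(params, n_passages, duration = 24,
                                     dt = 0.02, per_strain_dilution = NULL,
                                     seed = NULL, lag_jitter_sd = 0,
                                     instrument_tau = 0, rtol = 1e-8) {
  stopifnot(inherits(params, "community_params"))
  if (!is.numeric(n_passages) || n_passages < 1)
    stop_bad_arg("n_passages must be >= 1")
  n_passages <- as.integer(n_passages)
  sn <- names(params$strains)
  dil <- if (is.null(per_strain_dilution)) rep(1, length(sn)) else {
    if (is.null(names(per_strain_dilution)) &&
        length(per_strain_dilution) == length(sn))
      names(per_strain_dilution) <- sn
    named_or(per_strain_dilution, sn, 1)
  }
  if (any(dil <= 0)) stop_bad_arg("per_strain_dilution must be > 0")
  ad <- params$adaptation
  fresh <- params$substrates
  jitter <- matrix(0, n_passages, length(sn), dimnames = list(NULL, sn))
  if (lag_jitter_sd > 0) {
    a <- lag_jitter_sd * sqrt(3)  # uniform on [-a, a] has sd = a/sqrt(3)
    jitter[] <- with_seed(seed, stats::runif(n_passages * length(sn), -a, a))
  }
  out <- vector("list", n_passages)
  X0 <- params$initial_biomass * dil
  C0 <- params$substrates
  for (p in seq_len(n_passages)) {
    lag_shift <- jitter[p, ]
    mu_scale <- NULL
    if (!is.null(ad)) {
      off <- ad$factor^(p - 1)
      lag_shift <- lag_shift +
        vapply(params$strains, `[[`, 0, "lag_h") * ad$lag_excess * off
      mu_scale <- 1 - ad$mu_deficit * off
    }
    sim <- simulate_batch(params, duration = duration, dt = dt,
                          lag_shift = lag_shift, mu_scale = mu_scale,
                          initial_biomass = X0, substrates = C0,
                          instrument_tau = instrument_tau, rtol = rtol)
    sim$passage <- p
    out[[p]] <- sim
    nT <- length(sim$time)
    X0 <- params$transfer_fraction * sim$biomass[nT, ]
    C0 <- (1 - params$transfer_fraction) * named_or(fresh, colnames(sim$compounds), 0) +
      params$transfer_fraction * pmax(sim$compounds[nT, ], 0)
  }
  out
}

#' Extract the total heat-flow curve of a simulated batch
#'
#' Returns the measured (instrument-filtered) signal when the simulation
#' carried an instrument time constant, otherwise the instantaneous
#' metabolic heat flow.
#'
#' @param sim A `consortium_sim` object.
#' @param replicate,condition Labels attached to the series.
#' @return A [heatflow_series()].
#' @export
sim_heatflow_series <- function(sim, replicate = "r1", condition = "sim") {
  p <- if (is.null(sim$heat_flow_meas_total)) sim$heat_flow_total
  else sim$heat_flow_meas_total
  heatflow_series(sim$time, p, replicate = replicate,
                  passage = sim$passage, condition = condition)
}

#' @export
print.consortium_sim <- function(x, ...) {
  nT <- length(x$time)
  cat("<consortium_sim> passage", x$passage, "|", nT, "time points over",
      signif(x$time[nT], 4), "h\n")
  cat("  final biomass (gDW/L):",
      paste(sprintf("%s=%.4g", colnames(x$biomass), x$biomass[nT, ]),
            collapse = ", "), "\n")
  cat("  total heat released:", signif(x$cum_heat_total[nT], 4), "J\n")
  invisible(x)
}

#' Multinomial 16S read sampling from biomass fractions
#'
#' Forward model of amplicon sequencing: the expected read share of strain
#' i is proportional to its biomass fraction times its 16S rRNA gene copy
#' number; reads are a multinomial draw at the given depth.
#'
#' @param biomass_fractions Numeric vector of biomass fractions (must sum
#'   to 1 within 1e-6, all >= 0).
#' @param copy_numbers Integer vector of 16S copy numbers (>= 1).
#' @param depth Total number of reads (>= 1).
#' @param seed Seed for the draw.
#' @return Integer vector of read counts, named like the input.
#' @export
sample_reads <- function(biomass_fractions, copy_numbers, depth, seed = NULL) {
  f <- unlist(biomass_fractions)
  if (any(f < 0)) stop_bad_arg("biomass fractions must be >= 0")
  if (abs(sum(f) - 1) > 1e-6) stop_bad_arg("biomass fractions must sum to 1")
  cn <- as.numeric(unlist(copy_numbers))
  if (length(cn) != length(f)) stop_bad_arg("one copy number per strain required")
  if (any(cn < 1)) stop_bad_arg("copy numbers must be >= 1")
  depth <- as.integer(depth)
  if (is.na(depth) || depth < 1L) stop_bad_arg("depth must be >= 1")
  p <- f * cn
  p <- p / sum(p)
  reads <- with_seed(seed, as.integer(stats::rmultinom(1, depth, p)))
  names(reads) <- names(f)
  reads
}

#' Endpoint metabolite table from a simulated batch
#'
#' Emulates endpoint chromatographic quantification: start and end
#' concentrations of every compound, replicated with additive Gaussian
#' noise truncated at zero (concentrations cannot be negative).
#'
#' @param sim A `consortium_sim` object.
#' @param noise_sd Measurement noise standard deviation (mmol/L), scalar or
#'   named per metabolite.
#' @param n_replicates Number of technical/biological replicates (>= 1).
#' @param seed Seed for the noise draws.
#' @param sample Condition label stored in the table.
#' @param metabolites Optional subset of compound names to report.
#' @return A data.frame with columns `sample`, `replicate`, `metabolite`,
#'   `timepoint` ("start"/"end") and `conc_mM`.
#' @export
endpoint_metabolites <- function(sim, noise_sd = 0, n_replicates = 3,
                                 seed = NULL, sample = "sim",
                                 metabolites = NULL) {
  if (any(unlist(noise_sd) < 0)) stop_bad_arg("noise_sd must be >= 0")
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_replicates) || n_replicates < 1L)
    stop_bad_arg("n_replicates must be >= 1")
  mets <- if (is.null(metabolites)) colnames(sim$compounds) else
    intersect(metabolites, colnames(sim$compounds))
  if (length(mets) == 0) stop_bad_arg("no requested metabolite is tracked")
  start <- sim$compounds[1, mets]
  end <- pmax(sim$compounds[nrow(sim$compounds), mets], 0)
  sd_vec <- if (length(noise_sd) == 1L) rep(as.numeric(noise_sd), length(mets)) else
    named_or(noise_sd, mets, 0)
  grid <- expand.grid(replicate = seq_len(n_replicates), metabolite = mets,
                      timepoint = c("start", "end"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base <- ifelse(grid$timepoint == "start", start[grid$metabolite],
                 end[grid$metabolite])
  noise <- with_seed(seed, stats::rnorm(nrow(grid), 0,
                                        rep(sd_vec, length.out = length(mets))[
                                          match(grid$metabolite, mets)]))
  data.frame(sample = sample, replicate = grid$replicate,
             metabolite = grid$metabolite, timepoint = grid$timepoint,
             conc_mM = pmax(base + noise, 0), stringsAsFactors = FALSE)
}

#' Apply a first-order instrument response to a heat-flow series
#'
#' Isothermal microcalorimeters read heat flow through a thermopile with a
#' thermal time constant of minutes, so measured curves are low-pass
#' filtered relative to the instantaneous metabolic heat. This applies the
#' corresponding first-order exponential filter. A pure exponential phase
#' keeps its log-slope exactly (the filter only rescales it by
#' `1/(1 + mu*tau)`), while sub-minute features such as substrate-depletion
#' drops are smeared over `tau`.
#'
#' @param series A [heatflow_series()].
#' @param tau Instrument time constant (h).
#' @return A filtered `heatflow_series`.
#' @export
lowpass_series <- function(series, tau) {
  stopifnot(inherits(series, "heatflow_series"))
  if (tau <= 0) return(series)
  t <- series$time_h; p <- series$power_W
  out <- numeric(length(p))
  out[1] <- p[1]
  for (i in 2:length(p)) {
    a <- 1 - exp(-(t[i] - t[i - 1]) / tau)
    out[i] <- out[i - 1] + a * (p[i] - out[i - 1])
  }
  heatflow_series(t, out, replicate = series$replicate,
                  passage = series$passage, condition = series$condition)
}

#' Add measurement noise and baseline drift to a heat-flow series
#'
#' @param series A [heatflow_series()].
#' @param sd Additive Gaussian noise standard deviation (W).
#' @param drift Linear baseline drift (W/h); the value at time t gains
#'   `drift * t`.
#' @param seed Seed for the noise draw.
#' @return A new `heatflow_series`; the input is not modified.
#' @export
add_measurement_noise <- function(series, sd = 0, drift = 0, seed = NULL) {
  stopifnot(inherits(series, "heatflow_series"))
  if (!is_scalar_num(sd) || sd < 0) stop_bad_arg("sd must be a finite number >= 0")
  if (!is_scalar_num(drift)) stop_bad_arg("drift must be finite")
  noise <- if (sd > 0)
    with_seed(seed, stats::rnorm(length(series$time_h), 0, sd)) else 0
  heatflow_series(series$time_h,
                  series$power_W + noise + drift * series$time_h,
                  replicate = series$replicate, passage = series$passage,
                  condition = series$condition)
}
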