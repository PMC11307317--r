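## Packaged simulation scenarios.  Each YAML fixture defines a community,
## its passaging design and the designed ground truth (phase rates,
## stability passage, composition, recovery passage) used by the
## validation suite.

fixture_scenarios <- c("monoculture_am", "monoculture_bt", "monoculture_fp",
                       "consortium", "resilience_am", "resilience_bt",
                       "resilience_fp")

fixture_file <- function(scenario) {
  f <- system.file("extdata", "fixtures", paste0(scenario, ".yaml"),
                   package = "calorimix")
  if (!nzchar(f))
    stop_bad_arg("unknown scenario '", scenario, "'; valid scenarios: ",
                 paste(fixture_scenarios, collapse = ", "))
  f
}

#' Load a packaged simulation scenario
#'
#' @param scenario Scenario name (one of `monoculture_am`,
#'   `monoculture_bt`, `monoculture_fp`, `consortium`, `resilience_am`,
#'   `resilience_bt`, `resilience_fp`) or a path to a fixture YAML file.
#' @return An object of class `calorimix_fixture` bundling the community
#'   parameters, passaging design, noise settings and the designed truth.
#' @export
load_fixture <- function(scenario) {
  path <- if (file.exists(scenario)) scenario else fixture_file(scenario)
  fx <- yaml::read_yaml(path)
  if (!is.null(fx$base)) {
    base <- yaml::read_yaml(fixture_file(fx$base))
    for (key in setdiff(names(fx), "base")) base[[key]] <- fx[[key]]
    fx <- base
  }
  strains <- lapply(fx$strains, function(s) {
    strain_params(name = s$name, mu_max = s$mu_max, K = s$K,
                  yield_X = s$yield_X, yield_P = s$yield_P,
                  heat_yield = if (is.null(s$heat_yield_J_per_gDW)) 1500
                  else s$heat_yield_J_per_gDW,
                  copy_number = s$copy_number, lag_h = s$lag_h,
                  conversion = s$conversion)
  })
  params <- community_params(
    strains = strains, substrates = fx$medium,
    initial_biomass = fx$initial_biomass,
    transfer_fraction = fx$transfer_fraction,
    volume_L = fx$volume_L, adaptation = fx$adaptation)
  structure(list(
    scenario = fx$scenario, params = params,
    passages = fx$passages, duration = fx$duration_h, dt = fx$dt_h,
    replicates = fx$replicates,
    lag_jitter_sd = fx$lag_jitter_sd_h,
    measurement_noise = fx$measurement_noise_W,
    metabolite_noise = fx$metabolite_noise_mM,
    instrument_tau = if (is.null(fx$instrument_tau_h)) 0.05 else fx$instrument_tau_h,
    read_depth = fx$read_depth,
    abundance_interval = fx$abundance_interval_h,
    pca_grid = seq(fx$pca_grid$from, fx$pca_grid$to, by = fx$pca_grid$by),
    dilution = if (is.null(fx$dilution)) NULL else unlist(fx$dilution),
    copy_numbers = stats::setNames(
      vapply(strains, `[[`, 1L, "copy_number"),
      vapply(strains, `[[`, "", "name")),
    truth = fx$truth), class = "calorimix_fixture")
}

#' @export
print.calorimix_fixture <- function(x, ...) {
  cat("<calorimix_fixture>", x$scenario, "|",
      length(x$params$strains), "strain(s),", x$passages, "passages x",
      x$replicates, "replicates\n")
  invisible(x)
}

#' Run a packaged scenario
#'
#' Simulates all replicate ampoules over all passages, applying the
#' scenario's adaptation drift, replicate lag jitter, optional
#' passage-1 under-inoculation and measurement noise.
#'
#' @param fixture A [load_fixture()] object or scenario name.
#' @param seed Seed driving all stochastic elements.
#' @return List with `fixture`, `sims` (nested `[[replicate]][[passage]]`
#'   `consortium_sim` objects) and `series` (flat list of total
#'   heat-flow [heatflow_series()], condition = scenario name).
#' @export
run_scenario <- function(fixture, seed = 1) {
  if (is.character(fixture)) fixture <- load_fixture(fixture)
  sims <- vector("list", fixture$replicates)
  series <- list()
  for (r in seq_len(fixture$replicates)) {
    sims[[r]] <- simulate_serial_passages(
      fixture$params, n_passages = fixture$passages,
      duration = fixture$duration, dt = fixture$dt,
      per_strain_dilution = fixture$dilution,
      seed = derive_seed(seed, r), lag_jitter_sd = fixture$lag_jitter_sd,
      instrument_tau = fixture$instrument_tau)
    for (p in seq_len(fixture$passages)) {
      s <- sim_heatflow_series(sims[[r]][[p]],
                               replicate = sprintf("r%d", r),
                               condition = fixture$scenario)
      if (fixture$measurement_noise > 0)
        s <- add_measurement_noise(s, sd = fixture$measurement_noise,
                                   seed = derive_seed(seed, 100 * r + p))
      series[[length(series) + 1L]] <- s
    }
  }
  list(fixture = fixture, sims = sims, series = series)
}

#' End-of-passage community composition of a scenario run
#'
#' @param run A [run_scenario()] result.
#' @param replicate Replicate index.
#' @return Data.frame `passage`, `strain`, `fraction` (biomass fractions).
#' @export
endpoint_composition <- function(run, replicate = 1) {
  sims <- run$sims[[replicate]]
  do.call(rbind, lapply(sims, function(sim) {
    x <- sim$biomass[nrow(sim$biomass), ]
    data.frame(passage = sim$passage, strain = names(x),
               fraction = as.numeric(x / sum(x)), stringsAsFactors = FALSE)
  }))
}

#' Hourly 16S read sampling of a simulated consortium passage
#'
#' @param sim A `consortium_sim`.
#' @param copy_numbers Named 16S copy numbers.
#' @param depth Read depth per sample.
#' @param interval Sampling interval (h).
#' @param seed Seed.
#' @return An [abundance_table()].
#' @export
sample_abundance_series <- function(sim, copy_numbers, depth = 1e5,
                                    interval = 1, seed = NULL) {
  times <- seq(sim$time[1], sim$time[length(sim$time)], by = interval)
  rows <- lapply(seq_along(times), function(i) {
    j <- which.min(abs(sim$time - times[i]))
    x <- sim$biomass[j, ]
    f <- x / sum(x)
    reads <- sample_reads(f, copy_numbers[names(x)], depth,
                          seed = derive_seed(seed, i))
    data.frame(time_h = times[i], strain = names(x), reads = as.numeric(reads),
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  abundance_table(long$time_h, long$strain, long$reads, copy_numbers)
}

#' Generate fixture files for a scenario
#'
#' Writes the simulator outputs for one scenario in the pipeline's file
#' formats: the heat-flow CSV over all replicates and passages, an hourly
#' abundance TSV and per-passage composition table (multi-strain
#' scenarios), an endpoint metabolite CSV and the designed ground truth
#' as JSON. `scenario = "stability_suite"` generates the four stability
#' scenarios in subdirectories.
#'
#' @param scenario Scenario name (see [load_fixture()]) or
#'   `"stability_suite"`.
#' @param seed Seed; the same seed reproduces byte-identical files.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a named list of the written file paths.
#' @export
generate_fixtures <- function(scenario, seed = 1, outdir = ".") {
  if (identical(scenario, "stability_suite")) {
    out <- lapply(c("monoculture_am", "monoculture_bt", "monoculture_fp",
                    "consortium"), function(sc)
      generate_fixtures(sc, seed = seed, outdir = file.path(outdir, sc)))
    return(invisible(out))
  }
  fixture <- load_fixture(scenario)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  run <- run_scenario(fixture, seed = seed)
  paths <- list()
  paths$heatflow <- file.path(outdir, paste0(fixture$scenario, "_heatflow.csv"))
  write_heatflow_csv(run$series, paths$heatflow)
  last <- fixture$passages
  if (length(fixture$params$strains) > 1L) {
    ab <- sample_abundance_series(run$sims[[1]][[last]],
                                  fixture$copy_numbers,
                                  depth = fixture$read_depth,
                                  interval = fixture$abundance_interval,
                                  seed = derive_seed(seed, 7001))
    paths$abundance <- file.path(outdir, paste0(fixture$scenario, "_abundance.tsv"))
    write_abundance_tsv(ab, paths$abundance)
    comp <- endpoint_composition(run)
    reads <- do.call(rbind, lapply(split(comp, comp$passage), function(d) {
      rd <- sample_reads(d$fraction, fixture$copy_numbers[d$strain],
                         fixture$read_depth,
                         seed = derive_seed(seed, 8000 + d$passage[1]))
      data.frame(passage = d$passage, strain = d$strain,
                 reads = as.numeric(rd), stringsAsFactors = FALSE)
    }))
    paths$composition <- file.path(outdir,
                                   paste0(fixture$scenario, "_composition.tsv"))
    utils::write.table(reads, paths$composition, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  met <- endpoint_metabolites(run$sims[[1]][[last]],
                              noise_sd = fixture$metabolite_noise,
                              n_replicates = fixture$replicates,
                              seed = derive_seed(seed, 9001),
                              sample = fixture$scenario)
  paths$metabolites <- file.path(outdir,
                                 paste0(fixture$scenario, "_metabolites.csv"))
  write_metabolite_csv(met, paths$metabolites)
  truth <- fixture$truth
  truth$seed <- seed
  paths$truth <- file.path(outdir, paste0(fixture$scenario, "_truth.json"))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
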