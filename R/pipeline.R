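## End-to-end pipeline: wires fixture generation, kinetics, stability,
## composition, resilience, metabolite and constraint-based stages into a
## reproducible run driven by one config and one seed.

#' Validate a pipeline run configuration
#'
#' @param config A list or path to a YAML file with elements: `seed`
#'   (integer), `outdir` (output directory), `scenarios` (character,
#'   default the consortium plus the three monocultures),
#'   `resilience_scenarios` (default the three under-inoculation
#'   scenarios), `stages` (subset of `"simulate"`, `"kinetics"`,
#'   `"stability"`, `"composition"`, `"resilience"`, `"metabolites"`,
#'   `"fba"`; default all), `stability_k`, `gems` (paths to model files;
#'   default the packaged synthetic toy models) and `fba` options
#'   (`fraction`, `n_samples`).
#' @return The validated config (class `run_config`).
#' @export
run_config <- function(config) {
  src <- NULL
  if (is.character(config)) {
    if (!file.exists(config)) stop_bad_arg("config file not found: ", config)
    src <- config
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    seed = 1L, outdir = "calorimix_run",
    scenarios = c("consortium", "monoculture_am", "monoculture_bt",
                  "monoculture_fp"),
    resilience_scenarios = c("resilience_am", "resilience_bt", "resilience_fp"),
    stages = c("simulate", "kinetics", "stability", "composition",
               "resilience", "metabolites", "fba"),
    stability_k = 4,
    gems = file.path("extdata", "gems",
                     c("am_like_synthetic.json", "bt_like_synthetic.json",
                       "fp_like_synthetic.json")),
    fba = list(fraction = 0.9, n_samples = 200))
  for (k in names(defaults)) if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  bad <- setdiff(config$stages, defaults$stages)
  if (length(bad)) stop_bad_arg("unknown stage(s): ", paste(bad, collapse = ", "))
  all_sc <- c(config$scenarios,
              if ("resilience" %in% config$stages) config$resilience_scenarios)
  for (sc in all_sc) fixture_file_or_path(sc)   # fails early on bad names
  config$gems <- vapply(config$gems, function(p) {
    cand <- c(p, system.file(p, package = "calorimix"))
    cand <- cand[file.exists(cand) & nzchar(cand)]
    if (length(cand) == 0) stop_bad_arg("GEM file not found: ", p)
    cand[1]
  }, "")
  config$config_file <- src
  class(config) <- c("run_config", "list")
  config
}

fixture_file_or_path <- function(scenario) {
  if (file.exists(scenario)) scenario else fixture_file(scenario)
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order on simulated fixture
#' data: `simulate` writes the input files, `kinetics` estimates
#' phase-specific growth rates from the late stable passages, `stability`
#' detects the stability passage per scenario by PCA of heat-flow curves,
#' `composition` normalizes 16S reads and deconvolves consortium heat
#' into per-strain growth rates, `resilience` scores the
#' under-inoculation scenarios against the consortium reference,
#' `metabolites` compares consortium and stacked-monoculture endpoint
#' production, and `fba` runs measured-rate-constrained depletion screens
#' on the configured genome-scale models. A failing stage is recorded in
#' the manifest and downstream stages are skipped.
#'
#' @param config A [run_config()] (or list / YAML path coerced by it).
#' @return The run manifest (list, also written as JSON to the output
#'   directory): per-stage status, outputs, seed and config hash.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed,
                   config_hash = if (!is.null(config$config_file))
                     unname(tools::md5sum(config$config_file)) else NA,
                   started = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   stages = list())
  state <- new.env()
  failed <- FALSE
  for (stage in c("simulate", "kinetics", "stability", "composition",
                  "resilience", "metabolites", "fba")) {
    if (!(stage %in% config$stages)) next
    if (failed) {
      manifest$stages[[stage]] <- list(status = "skipped")
      next
    }
    t0 <- Sys.time()
    res <- tryCatch(
      list(status = "ok",
           outputs = do.call(paste0("stage_", stage), list(config, state))),
      error = function(e) list(status = "failed",
                               error = conditionMessage(e)))
    res$wall_s <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
    message(sprintf("[calorimix] stage %-12s %s (%.1fs)", stage, res$status,
                    res$wall_s))
    manifest$stages[[stage]] <- res
    if (res$status == "failed") failed <- TRUE
  }
  manifest$ok <- !failed
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

stage_simulate <- function(config, state) {
  out <- list()
  for (sc in c(config$scenarios, config$resilience_scenarios)) {
    paths <- generate_fixtures(sc, seed = config$seed,
                               outdir = file.path(config$outdir, "data", sc))
    out[[sc]] <- unlist(paths)
  }
  state$data <- out
  unlist(out)
}

scenario_series <- function(config, sc) {
  read_heatflow_csv(file.path(config$outdir, "data", sc,
                              paste0(sc, "_heatflow.csv")))
}

stage_kinetics <- function(config, state) {
  rows <- list()
  for (sc in config$scenarios) {
    series <- scenario_series(config, sc)
    late <- Filter(function(s) s$passage >= 5, series)
    for (s in late) {
      ph <- segment_phases(s, max_phases = 3)
      rows[[length(rows) + 1L]] <-
        cbind(condition = sc, passage = s$passage, replicate = s$replicate,
              phase = seq_len(nrow(ph)), ph)
    }
  }
  df <- do.call(rbind, rows)
  path <- file.path(config$outdir, "growth_rates.csv")
  utils::write.csv(df, path, row.names = FALSE)
  state$kinetics <- df
  path
}

stage_stability <- function(config, state) {
  state$stability <- list()
  out <- character(0)
  for (sc in c(config$scenarios)) {
    fx <- load_fixture(sc)
    m <- assemble_passage_matrix(scenario_series(config, sc), fx$pca_grid)
    ## 10 retained components: the stability detector uses the first two,
    ## the resilience projection the full retained space
    pca <- pca_scores(m, scale. = FALSE, n_components = 10)
    rep <- detect_stable_passage(pca, k = config$stability_k)
    state$stability[[sc]] <- list(pca = pca, report = rep)
    path <- file.path(config$outdir, paste0("stability_", sc, ".json"))
    jsonlite::write_json(
      list(scenario = sc, passages_to_stability = rep$passages_to_stability,
           reached = rep$reached, d_w = rep$d_w, k = rep$k,
           shifts = as.list(rep$shifts),
           centroids = apply(rep$centroids, 1, as.list)),
      path, auto_unbox = TRUE, digits = NA, null = "null")
    scores_path <- file.path(config$outdir, paste0("scores_", sc, ".csv"))
    utils::write.csv(data.frame(row = rownames(pca$scores),
                                passage = pca$passage,
                                replicate = pca$replicate, pca$scores),
                     scores_path, row.names = FALSE)
    out <- c(out, path, scores_path)
  }
  out
}

stage_composition <- function(config, state) {
  sc <- "consortium"
  if (!(sc %in% config$scenarios)) return(character(0))
  fx <- load_fixture(sc)
  ab <- read_abundance_tsv(file.path(config$outdir, "data", sc,
                                     paste0(sc, "_abundance.tsv")),
                           fx$copy_numbers)
  series <- scenario_series(config, sc)
  last <- Filter(function(s) s$passage == fx$passages & s$replicate == "r1",
                 series)[[1]]
  total <- baseline_and_integrate(last, baseline_window = 0)
  curves <- reconstruct_strain_heat(total, ab)
  rates <- strain_growth_rates_in_consortium(curves, max_phases = 3)
  df <- do.call(rbind, lapply(names(rates), function(s)
    if (nrow(rates[[s]])) cbind(strain = s, phase = seq_len(nrow(rates[[s]])),
                                rates[[s]]) else NULL))
  path <- file.path(config$outdir, "consortium_strain_rates.csv")
  utils::write.csv(df, path, row.names = FALSE)
  comp <- stats::aggregate(fraction ~ strain, data = ab[ab$time_h == max(ab$time_h), ],
                           FUN = sum)
  path2 <- file.path(config$outdir, "consortium_composition.csv")
  utils::write.csv(comp, path2, row.names = FALSE)
  state$composition <- list(abundance = ab, rates = rates)
  c(path, path2)
}

stage_resilience <- function(config, state) {
  ref <- state$stability[["consortium"]]
  if (is.null(ref)) stop("resilience requires the consortium stability stage")
  out <- character(0)
  for (sc in config$resilience_scenarios) {
    fx <- load_fixture(sc)
    m <- assemble_passage_matrix(scenario_series(config, sc), fx$pca_grid)
    res <- assess_resilience(m, ref$pca, ref$report, k = config$stability_k)
    comp_path <- file.path(config$outdir, "data", sc,
                           paste0(sc, "_composition.tsv"))
    comp <- utils::read.delim(comp_path)
    fr <- do.call(rbind, lapply(split(comp, comp$passage), function(d) {
      data.frame(passage = d$passage, strain = d$strain,
                 fraction = normalize_by_copy_number(
                   d$reads, fx$copy_numbers[d$strain]))
    }))
    ref_comp <- unlist(fx$truth$composition)
    crec <- composition_recovery(fr, ref_comp, tol = 0.05)
    path <- file.path(config$outdir, paste0("resilience_", sc, ".json"))
    jsonlite::write_json(
      list(scenario = sc, kinetic_recovery_passage = res$recovery_passage,
           recovered = res$recovered, distances = as.list(res$distances),
           threshold = res$threshold,
           composition_recovery_passage = crec$recovery_passage),
      path, auto_unbox = TRUE, digits = NA, null = "null")
    out <- c(out, path)
  }
  out
}

stage_metabolites <- function(config, state) {
  read_tab <- function(sc) read_metabolite_csv(
    file.path(config$outdir, "data", sc, paste0(sc, "_metabolites.csv")))
  monos <- config$scenarios[startsWith(config$scenarios, "monoculture")]
  if (!("consortium" %in% config$scenarios) || length(monos) == 0)
    return(character(0))
  cons <- read_tab("consortium")
  mono_tables <- lapply(monos, read_tab)
  names(mono_tables) <- monos
  cmp <- compare_consortium_vs_stack(mono_tables, cons)
  path <- file.path(config$outdir, "metabolite_comparison.csv")
  utils::write.csv(cmp, path, row.names = FALSE)
  state$metabolites <- cmp
  path
}

stage_fba <- function(config, state) {
  out <- character(0)
  for (gp in config$gems) {
    model <- load_gem(gp)
    scr <- depletion_screen(model)
    path <- file.path(config$outdir,
                      paste0("depletion_", model$id, ".csv"))
    df <- scr
    df$mu_reference <- attr(scr, "mu_reference")
    utils::write.csv(df, path, row.names = FALSE)
    fv <- fva(model, fraction = config$fba$fraction)
    sp <- sample_fluxes(model, n = config$fba$n_samples,
                        fraction = config$fba$fraction,
                        seed = derive_seed(config$seed, 31L))
    path2 <- file.path(config$outdir, paste0("fluxes_", model$id, ".csv"))
    utils::write.csv(merge(fv, sp, by = "reaction"), path2, row.names = FALSE)
    out <- c(out, path, path2)
  }
  out
}
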