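#' Strain growth parameters
#'
#' Bundles the kinetic and stoichiometric description of one strain for the
#' consortium batch simulator: Monod growth on one or more substrates,
#' biomass and product yields, growth-associated heat yield, 16S rRNA gene
#' copy number and a lag time.
#'
#' @param name Strain label.
#' @param mu_max Named numeric vector, maximum specific growth rate
#'   (h^-1) per substrate. At least one entry must be positive.
#' @param K Named numeric vector, Monod half-saturation constants
#'   (mmol/L) per substrate. Missing substrates default to 0.01 mmol/L.
#' @param yield_X Named numeric vector, biomass yield (gDW per mmol)
#'   per substrate. Missing substrates default to 0.02 gDW/mmol.
#' @param yield_P Named list of named numeric vectors:
#'   `yield_P[[product]][substrate]` is the product formed
#'   (mmol per mmol substrate consumed through growth).
#' @param heat_yield Heat released per gram dry weight of new biomass
#'   (J/gDW). Shared default 1500 J/gDW.
#' @param copy_number Integer 16S rRNA gene copy number (>= 1).
#' @param lag_h Lag time before growth starts (h).
#' @param conversion Optional non-growth-associated conversion, a list with
#'   elements `substrate`, `product`, `v_max` (mmol/gDW/h), `K` (mmol/L)
#'   and `yield` (mmol product per mmol substrate). Used for
#'   cross-feeding conversions that are uncoupled from biomass formation,
#'   such as acetate-dependent butyrate formation.
#'
#' @return An object of class `strain_params`.
#' @export
strain_params <- function(name, mu_max, K = NULL, yield_X = NULL,
                          yield_P = NULL, heat_yield = 1500,
                          copy_number = 1L, lag_h = 0,
                          conversion = NULL) {
  mu_max <- unlist(mu_max)
  if (is.null(names(mu_max)) || any(!nzchar(names(mu_max))))
    stop_bad_arg("mu_max must be a named vector (names are substrates)")
  if (any(mu_max < 0)) stop_bad_arg("mu_max entries must be >= 0")
  if (!any(mu_max > 0))
    stop_bad_arg("strain '", name, "' needs at least one substrate with mu_max > 0")
  subs <- names(mu_max)
  K <- named_or(K, subs, default = 0.01)
  yield_X <- named_or(yield_X, subs, default = 0.02)
  if (any(K <= 0)) stop_bad_arg("half-saturation constants must be > 0")
  if (any(yield_X <= 0)) stop_bad_arg("biomass yields must be > 0")
  if (!is.null(yield_P)) {
    if (is.null(names(yield_P))) stop_bad_arg("yield_P must be a named list")
    yield_P <- lapply(yield_P, unlist)
    if (any(unlist(yield_P) < 0)) stop_bad_arg("product yields must be >= 0")
  }
  if (!is_scalar_num(heat_yield) || heat_yield < 0)
    stop_bad_arg("heat_yield must be a non-negative number (J/gDW)")
  copy_number <- as.integer(copy_number)
  if (is.na(copy_number) || copy_number < 1L)
    stop_bad_arg("copy_number must be an integer >= 1")
  if (!is_scalar_num(lag_h) || lag_h < 0) stop_bad_arg("lag_h must be >= 0")
  if (!is.null(conversion)) {
    need <- c("substrate", "product", "v_max", "K")
    if (!all(need %in% names(conversion)))
      stop_bad_arg("conversion needs elements: ", paste(need, collapse = ", "))
    if (is.null(conversion$yield)) conversion$yield <- 1
    if (conversion$v_max < 0 || conversion$K <= 0 || conversion$yield < 0)
      stop_bad_arg("invalid conversion kinetics")
  }
  structure(list(name = as.character(name), mu_max = mu_max, K = K,
                 yield_X = yield_X, yield_P = yield_P,
                 heat_yield = heat_yield, copy_number = copy_number,
                 lag_h = lag_h, conversion = conversion),
            class = "strain_params")
}

#' Community (consortium) parameters
#'
#' @param strains List of [strain_params()] objects.
#' @param substrates Named numeric vector of initial medium concentrations
#'   (mmol/L). Products that start at zero may be omitted.
#' @param initial_biomass Named numeric vector, inoculum biomass per strain
#'   (gDW/L).
#' @param transfer_fraction Fraction of culture transferred at each passage
#'   (v/v), default 0.01 (1 percent).
#' @param volume_L Working volume of one ampoule in litres (default 0.002).
#' @param adaptation Optional passage-dependent adaptation drift, a list
#'   with elements `lag_excess` (named per strain or scalar; relative
#'   excess of the lag time at passage 1), `mu_deficit` (relative deficit
#'   of all mu_max at passage 1) and `factor` (per-passage geometric
#'   convergence factor in `[0, 1)`). At passage p the lag is
#'   `lag_h * (1 + lag_excess * factor^(p-1))` and the growth rates are
#'   scaled by `1 - mu_deficit * factor^(p-1)`.
#'
#' @return An object of class `community_params`.
#' @export
community_params <- function(strains, substrates, initial_biomass,
                             transfer_fraction = 0.01, volume_L = 0.002,
                             adaptation = NULL) {
  if (inherits(strains, "strain_params")) strains <- list(strains)
  stopifnot(length(strains) >= 1L,
            all(vapply(strains, inherits, TRUE, "strain_params")))
  strain_names <- vapply(strains, `[[`, "", "name")
  if (anyDuplicated(strain_names)) stop_bad_arg("duplicate strain names")
  names(strains) <- strain_names
  substrates <- unlist(substrates)
  if (is.null(names(substrates))) stop_bad_arg("substrates must be named")
  if (any(substrates < 0)) stop_bad_arg("substrate concentrations must be >= 0")
  initial_biomass <- named_or(initial_biomass, strain_names, default = NA)
  if (anyNA(initial_biomass))
    stop_bad_arg("initial_biomass must cover every strain")
  if (any(initial_biomass < 0)) stop_bad_arg("initial_biomass must be >= 0")
  if (!is_scalar_num(transfer_fraction) ||
      transfer_fraction <= 0 || transfer_fraction >= 1)
    stop_bad_arg("transfer_fraction must be in (0, 1)")
  if (!is_scalar_num(volume_L) || volume_L <= 0)
    stop_bad_arg("volume_L must be > 0")
  if (!is.null(adaptation)) {
    adaptation$factor <- if (is.null(adaptation$factor)) 0.5 else adaptation$factor
    if (adaptation$factor < 0 || adaptation$factor >= 1)
      stop_bad_arg("adaptation factor must be in [0, 1)")
    adaptation$lag_excess <- named_or(adaptation$lag_excess, strain_names, 0)
    adaptation$mu_deficit <- named_or(adaptation$mu_deficit, strain_names, 0)
    if (any(adaptation$mu_deficit >= 1))
      stop_bad_arg("mu_deficit must be < 1")
  }
  structure(list(strains = strains, substrates = substrates,
                 initial_biomass = initial_biomass,
                 transfer_fraction = transfer_fraction,
                 volume_L = volume_L, adaptation = adaptation),
            class = "community_params")
}

#' Passage at which an adaptation schedule has converged
#'
#' First passage at which the relative parameter offset of the drift
#' schedule has decayed to at most `tol` (default 1 percent) of the
#' asymptotic value.
#'
#' @param adaptation Adaptation list as in [community_params()].
#' @param tol Relative offset defining convergence (default 0.01).
#' @return Integer passage index (1 if there is no drift).
#' @export
convergence_passage <- function(adaptation, tol = 0.01) {
  if (is.null(adaptation)) return(1L)
  eps0 <- max(adaptation$lag_excess, adaptation$mu_deficit)
  if (eps0 <= tol) return(1L)
  r <- adaptation$factor
  if (r == 0) return(2L)
  1L + as.integer(ceiling(log(tol / eps0) / log(r)))
}

#' @export
print.strain_params <- function(x, ...) {
  cat("<strain_params>", x$name, "\n")
  cat("  substrates:", paste(names(x$mu_max), collapse = ", "), "\n")
  cat("  mu_max (h^-1):", paste(signif(x$mu_max, 3), collapse = ", "), "\n")
  cat("  16S copies:", x$copy_number, " lag:", x$lag_h, "h\n")
  invisible(x)
}

#' @export
print.community_params <- function(x, ...) {
  cat("<community_params>", length(x$strains), "strain(s):",
      paste(names(x$strains), collapse = ", "), "\n")
  cat("  transfer fraction:", x$transfer_fraction,
      " volume:", x$volume_L * 1000, "mL\n")
  invisible(x)
}
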