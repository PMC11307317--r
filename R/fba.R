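## Constraint-based analysis: flux balance analysis (FBA), measured-rate
## constraints, substrate-depletion screens, flux variability analysis
## (FVA) and random-objective flux sampling.
##
## The linear programs are solved with the package's two-phase simplex
## (see simplex.R) after shifting fluxes to non-negative variables:
## w = v - lb, S w = -S lb, 0 <= w <= ub - lb.  Infinite bounds are boxed
## at +/- `big` (default 1000, the conventional GEM bound).

solve_lp <- function(obj, S, lb, ub, ineq_A = NULL, ineq_b = NULL,
                     maximize = TRUE, big = 1000) {
  inf_lb <- !is.finite(lb); inf_ub <- !is.finite(ub)
  lb[inf_lb] <- -big; ub[inf_ub] <- big
  n <- length(lb)
  A_eq <- S
  b_eq <- as.numeric(-S %*% lb)
  flip <- b_eq < 0
  A_eq[flip, ] <- -A_eq[flip, , drop = FALSE]
  b_eq[flip] <- -b_eq[flip]
  A_le <- diag(n); b_le <- ub - lb
  if (!is.null(ineq_A)) {            # rows: a' v >= b
    ineq_A <- matrix(ineq_A, ncol = n)
    bw <- ineq_b - as.numeric(ineq_A %*% lb)
    for (i in seq_along(bw)) {
      if (bw[i] <= 0) {              # slack at w = 0: fold into <=
        A_le <- rbind(A_le, -ineq_A[i, ]); b_le <- c(b_le, -bw[i])
      } else {                       # treat as equality-free >=: flip sign
        A_eq <- rbind(A_eq, ineq_A[i, ])
        b_eq <- c(b_eq, bw[i])
        ## a >= row is encoded as equality plus a surplus variable; to keep
        ## the solver interface minimal, rewrite  a'w >= b  as
        ## -a'w <= -b ... not allowed (negative rhs), so append a surplus
        ## column through the equality mechanism below.
      }
    }
  }
  ## >= rows appended to A_eq above need surplus variables: extend the
  ## system with one non-negative surplus column per such row.
  n_ge <- nrow(A_eq) - nrow(S)
  if (n_ge > 0) {
    A_eq <- cbind(A_eq, matrix(0, nrow(A_eq), n_ge))
    for (i in seq_len(n_ge)) A_eq[nrow(S) + i, n + i] <- -1
    A_le <- cbind(A_le, matrix(0, nrow(A_le), n_ge))
    obj_full <- c(obj, rep(0, n_ge))
  } else obj_full <- obj
  sol <- simplex_solve(if (maximize) -obj_full else obj_full,
                       A_le = A_le, b_le = b_le, A_eq = A_eq, b_eq = b_eq)
  status <- sol$status
  if (status != "optimal")
    return(list(status = status, objective = NA_real_,
                fluxes = rep(NA_real_, n), hit_artificial = FALSE))
  v <- sol$x[seq_len(n)] + lb
  list(status = status, objective = sum(obj * v), fluxes = v,
       hit_artificial = any(inf_ub & v > big - 1e-6) ||
         any(inf_lb & v < -big + 1e-6))
}

#' Flux balance analysis
#'
#' Maximizes the model objective (biomass production) by linear
#' programming over the steady-state flux polytope
#' `S v = 0, lb <= v <= ub`. Returns one optimal vertex; with degenerate
#' optima the vertex is solver-dependent, so downstream assertions should
#' target the objective value, FVA intervals or sampled statistics.
#'
#' @param model A [gem()].
#' @return An object of class `flux_result`: `objective` (the predicted
#'   growth rate when the objective is biomass, h^-1), named `fluxes`,
#'   and `status` (`"optimal"`, `"infeasible"` or `"unbounded"`).
#' @export
fba <- function(model) {
  stopifnot(inherits(model, "gem"))
  sol <- solve_lp(model$obj, model$S, model$lb, model$ub)
  if (sol$status == "optimal" && sol$hit_artificial) {
    wide <- solve_lp(model$obj, model$S, model$lb, model$ub, big = 1e6)
    if (wide$status == "optimal" &&
        wide$objective > sol$objective + 1e-6 * (1 + abs(sol$objective))) {
      return(structure(list(objective = NA_real_,
                            fluxes = rep(NA_real_, length(model$lb)),
                            status = "unbounded"), class = "flux_result"))
    }
    sol <- wide
  }
  status <- if (sol$status == "optimal") "optimal" else "infeasible"
  fl <- sol$fluxes
  names(fl) <- model$reactions
  structure(list(objective = sol$objective, fluxes = fl, status = status),
            class = "flux_result")
}

#' @export
print.flux_result <- function(x, ...) {
  cat("<flux_result>", x$status)
  if (x$status == "optimal")
    cat(", objective =", signif(x$objective, 6))
  cat("\n")
  invisible(x)
}

#' Constrain exchange reactions with measured uptake/production rates
#'
#' Each measured rate (negative = consumption) becomes an exchange-flux
#' window `[rate - sd, rate + sd]`, clipped into the model's original
#' bounds so an infeasible orientation (e.g. forcing production of a
#' substrate the model cannot produce) is rejected. A rate of 0 with sd 0
#' fixes the exchange to zero (depletion semantics).
#'
#' @param model A [gem()].
#' @param rates Data.frame with columns `metabolite`, `rate`
#'   (mmol/gDW/h) and optionally `sd`.
#' @param sd_mode `"span"` uses `rate +/- sd` windows, `"fixed"` pins the
#'   flux at `rate`.
#' @param met_map Optional named character vector mapping metabolite names
#'   to exchange-reaction ids, for metabolites that do not follow the
#'   `EX_<name>_e` convention.
#' @return The constrained `gem`.
#' @export
apply_measured_constraints <- function(model, rates,
                                       sd_mode = c("span", "fixed"),
                                       met_map = NULL) {
  sd_mode <- match.arg(sd_mode)
  stopifnot(inherits(model, "gem"),
            all(c("metabolite", "rate") %in% names(rates)))
  sdv <- if ("sd" %in% names(rates) && sd_mode == "span")
    ifelse(is.na(rates$sd), 0, rates$sd) else rep(0, nrow(rates))
  rxn <- vapply(rates$metabolite, function(m) {
    if (!is.null(met_map) && m %in% names(met_map)) met_map[[m]]
    else find_exchange(model, m)
  }, "")
  if (anyNA(rxn))
    stop("no exchange reaction found for metabolite(s): ",
         paste(rates$metabolite[is.na(rxn)], collapse = ", "), call. = FALSE)
  for (i in seq_len(nrow(rates))) {
    lo <- max(rates$rate[i] - sdv[i], model$lb[rxn[i]])
    hi <- min(rates$rate[i] + sdv[i], model$ub[rxn[i]])
    if (lo > hi)
      stop("measured rate for '", rates$metabolite[i],
           "' is outside the feasible orientation of ", rxn[i], call. = FALSE)
    model$lb[rxn[i]] <- lo
    model$ub[rxn[i]] <- hi
  }
  model
}

#' Substrate depletion screen
#'
#' Mimics removal of each substrate from the medium by setting the uptake
#' bound of its exchange reaction to zero and re-solving the FBA. A
#' substrate is `"essential"` when growth collapses (objective below
#' `essential_tol`), `"limiting"` when the objective drops below
#' `limiting_frac` of the reference optimum, and `"dispensable"`
#' otherwise. The model is restored between trials and solver failures
#' are recorded per row without aborting the screen.
#'
#' @param model A [gem()].
#' @param exchanges Exchange reaction ids to deplete (default: all
#'   exchanges with a negative lower bound, i.e. permitted uptakes).
#' @param essential_tol Objective below which growth counts as stopped.
#' @param limiting_frac Fraction of the reference optimum defining
#'   "limiting".
#' @return Data.frame with `exchange`, `mu_pred`, `status` and
#'   `classification`, plus the reference optimum as an attribute
#'   `mu_reference`.
#' @export
depletion_screen <- function(model, exchanges = NULL, essential_tol = 1e-6,
                             limiting_frac = 0.95) {
  stopifnot(inherits(model, "gem"))
  if (is.null(exchanges))
    exchanges <- names(model$exchanges)[model$lb[names(model$exchanges)] < 0]
  missing <- setdiff(exchanges, model$reactions)
  if (length(missing))
    stop_bad_arg("unknown exchange reaction(s): ", paste(missing, collapse = ", "))
  ref <- fba(model)
  if (ref$status != "optimal")
    stop("reference model is ", ref$status, call. = FALSE)
  rows <- lapply(exchanges, function(ex) {
    m2 <- model
    m2$lb[ex] <- max(m2$lb[ex], 0)
    if (m2$ub[ex] < m2$lb[ex]) m2$ub[ex] <- m2$lb[ex]
    sol <- tryCatch(fba(m2), error = function(e) {
      structure(list(objective = NA_real_, status = conditionMessage(e)),
                class = "flux_result")
    })
    mu <- if (identical(sol$status, "optimal")) sol$objective else 0
    cls <- if (!identical(sol$status, "optimal") || mu < essential_tol)
      "essential"
    else if (mu < limiting_frac * ref$objective) "limiting"
    else "dispensable"
    data.frame(exchange = ex, mu_pred = mu, status = sol$status,
               classification = cls, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "mu_reference") <- ref$objective
  out
}

## Shared constraint set for FVA and sampling: the polytope restricted to
## at least `fraction` of the optimal objective.
fraction_constraint <- function(model, fraction) {
  if (fraction <= 0 || fraction > 1)
    stop_bad_arg("fraction must be in (0, 1]")
  ref <- fba(model)
  if (ref$status != "optimal")
    stop("model is ", ref$status, "; cannot constrain to fraction of optimum",
         call. = FALSE)
  list(A = matrix(model$obj, nrow = 1), b = fraction * ref$objective,
       mu_opt = ref$objective)
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux subject to the model constraints
#' and to retaining at least `fraction` of the optimal objective.
#'
#' @param model A [gem()].
#' @param fraction Required fraction of the optimum, in (0, 1].
#' @return Data.frame with `reaction`, `min`, `max`; attribute
#'   `mu_optimum` carries the unconstrained optimum.
#' @export
fva <- function(model, fraction = 1.0) {
  stopifnot(inherits(model, "gem"))
  fc <- fraction_constraint(model, fraction)
  n <- length(model$reactions)
  lo <- hi <- numeric(n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- 1
    for (dir in c(FALSE, TRUE)) {
      sol <- solve_lp(e, model$S, model$lb, model$ub,
                      ineq_A = fc$A, ineq_b = fc$b, maximize = dir)
      if (sol$status != "optimal")
        stop("FVA subproblem for reaction '", model$reactions[j],
             "' returned status: ", sol$status, call. = FALSE)
      if (dir) hi[j] <- sol$objective else lo[j] <- sol$objective
    }
  }
  out <- data.frame(reaction = model$reactions, min = lo, max = hi,
                    stringsAsFactors = FALSE)
  attr(out, "mu_optimum") <- fc$mu_opt
  out
}

#' Random-objective flux sampling within the near-optimal polytope
#'
#' Solves `n` linear programs with independent random objective directions
#' (uniform on the unit sphere) inside the polytope restricted to
#' `fraction` of the optimal growth, and summarizes each reaction's
#' optimal-vertex fluxes by mean and standard deviation.
#'
#' @param model A [gem()].
#' @param n Number of samples.
#' @param fraction Required fraction of the optimum, in (0, 1].
#' @param seed Seed for the objective directions.
#' @return Data.frame with `reaction`, `mean`, `sd` and attribute
#'   `sd_defined` (FALSE with a single sample, where sd is reported as 0).
#' @export
sample_fluxes <- function(model, n, fraction = 0.9, seed = NULL) {
  stopifnot(inherits(model, "gem"))
  if (n < 1) stop_bad_arg("n must be >= 1")
  fc <- fraction_constraint(model, fraction)
  nr <- length(model$reactions)
  dirs <- with_seed(seed, matrix(stats::rnorm(n * nr), n, nr))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  V <- matrix(NA_real_, n, nr)
  for (i in seq_len(n)) {
    sol <- solve_lp(dirs[i, ], model$S, model$lb, model$ub,
                    ineq_A = fc$A, ineq_b = fc$b, maximize = TRUE)
    if (sol$status != "optimal")
      stop("sampling subproblem ", i, " returned status: ", sol$status,
           call. = FALSE)
    V[i, ] <- sol$fluxes
  }
  sds <- if (n == 1) rep(0, nr) else apply(V, 2, stats::sd)
  out <- data.frame(reaction = model$reactions, mean = colMeans(V), sd = sds,
                    stringsAsFactors = FALSE)
  attr(out, "sd_defined") <- n > 1
  attr(out, "mu_optimum") <- fc$mu_opt
  out
}

#' Steady-state residual of a flux vector
#'
#' @param model A [gem()].
#' @param fluxes Named or ordered flux vector.
#' @return `max |S v|`, the largest mass-balance violation.
#' @export
flux_balance_residual <- function(model, fluxes) {
  max(abs(model$S %*% as.numeric(fluxes)))
}
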