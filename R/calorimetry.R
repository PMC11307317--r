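#' Heat-flow series from one calorimeter ampoule
#'
#' @param time_h Strictly increasing time grid (h), at least 3 points.
#' @param power_W Heat flow (W), finite.
#' @param replicate,passage,condition Labels (replicate id, 1-based passage
#'   index, condition name).
#' @return An object of class `heatflow_series`.
#' @export
heatflow_series <- function(time_h, power_W, replicate = "r1", passage = 1L,
                            condition = "") {
  time_h <- as.numeric(time_h); power_W <- as.numeric(power_W)
  if (length(time_h) < 3L) stop_bad_arg("a heat-flow series needs >= 3 points")
  if (length(power_W) != length(time_h))
    stop_bad_arg("time and power lengths differ")
  if (any(!is.finite(time_h)) || any(!is.finite(power_W)))
    stop_bad_arg("heat-flow series values must be finite")
  if (any(diff(time_h) <= 0)) stop_bad_arg("times must be strictly increasing")
  passage <- as.integer(passage)
  if (is.na(passage) || passage < 1L) stop_bad_arg("passage must be >= 1")
  structure(list(time_h = time_h, power_W = power_W,
                 replicate = as.character(replicate), passage = passage,
                 condition = as.character(condition)),
            class = "heatflow_series")
}

#' @export
print.heatflow_series <- function(x, ...) {
  cat("<heatflow_series>", x$condition, "passage", x$passage, "replicate",
      x$replicate, "|", length(x$time_h), "points,",
      signif(x$time_h[1], 4), "-", signif(max(x$time_h), 4), "h, peak",
      signif(max(x$power_W) * 1e6, 4), "uW\n")
  invisible(x)
}

#' Baseline-correct a heat-flow series and integrate it to total heat
#'
#' The baseline is the median power over the initial `baseline_window` hours
#' (0 skips correction); the corrected power is integrated by the
#' trapezoidal rule, with time converted from hours to seconds, so that
#' `Q(t0) = 0` and heat is in joules.
#'
#' @param series A [heatflow_series()].
#' @param baseline_window Length of the initial baseline window (h).
#' @return An object of class `heat_curve`: `time_h`, `heat_J`, the
#'   subtracted `baseline_W`, the baseline-window noise `baseline_sd_W`,
#'   the corrected `power_W` and the source labels.
#' @export
baseline_and_integrate <- function(series, baseline_window = 0) {
  stopifnot(inherits(series, "heatflow_series"))
  if (!is_scalar_num(baseline_window) || baseline_window < 0)
    stop_bad_arg("baseline_window must be >= 0")
  t <- series$time_h; p <- series$power_W
  if (baseline_window >= max(t) - t[1])
    stop_bad_arg("baseline_window must be shorter than the series")
  baseline <- 0; baseline_sd <- 0
  if (baseline_window > 0) {
    idx <- which(t <= t[1] + baseline_window)
    if (length(idx) < 3L)
      stop_bad_arg("baseline window covers fewer than 3 points")
    baseline <- stats::median(p[idx])
    baseline_sd <- stats::sd(p[idx])
  }
  corr <- p - baseline
  structure(list(time_h = t, heat_J = cumtrapz(t, corr) * 3600,
                 power_W = corr, baseline_W = baseline,
                 baseline_sd_W = baseline_sd,
                 replicate = series$replicate, passage = series$passage,
                 condition = series$condition,
                 provenance = sprintf("median baseline over initial %g h",
                                      baseline_window)),
            class = "heat_curve")
}

#' @export
print.heat_curve <- function(x, ...) {
  cat("<heat_curve>", x$condition, "passage", x$passage, "replicate",
      x$replicate, "|", length(x$time_h), "points, total",
      signif(x$heat_J[length(x$heat_J)], 4), "J\n")
  invisible(x)
}

## Power signal of either input class.  For a heat curve without a stored
## power trace the heat is differentiated by central differences.
signal_power <- function(x) {
  if (inherits(x, "heatflow_series")) return(list(t = x$time_h, p = x$power_W))
  if (inherits(x, "heat_curve")) {
    if (!is.null(x$power_W)) return(list(t = x$time_h, p = x$power_W))
    t <- x$time_h; q <- x$heat_J
    n <- length(t)
    p <- numeric(n)
    p[2:(n - 1)] <- (q[3:n] - q[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
    p[1] <- (q[2] - q[1]) / (t[2] - t[1])
    p[n] <- (q[n] - q[n - 1]) / (t[n] - t[n - 1])
    return(list(t = t, p = p / 3600))
  }
  stop_bad_arg("expected a heatflow_series or heat_curve")
}

#' Estimate a specific growth rate on a time window
#'
#' Under exponential growth with growth-associated heat release both the
#' heat flow and (asymptotically) the accumulated heat grow as
#' `exp(mu * t)`, so `mu` is the least-squares slope of the log signal
#' against time. The default regresses `ln(heat flow)`, which is exact for
#' exponential growth at all times; `"heat-log"` regresses `ln(total heat)`
#' which approaches the same slope from above only once
#' `exp(mu*t) >> 1`, i.e. it is biased upward early in the phase.
#'
#' @param x A [heatflow_series()] or [heat_curve()][baseline_and_integrate].
#' @param window Numeric length-2 vector, time window (h).
#' @param method `"heatflow-log"` (default) or `"heat-log"`.
#' @param min_points Minimum number of usable points in the window.
#' @return A one-row data.frame of class `growth_phase` with `t_start`,
#'   `t_end`, `mu` (h^-1), `fit_r2` and `n_points`.
#' @export
estimate_growth_rate <- function(x, window,
                                 method = c("heatflow-log", "heat-log"),
                                 min_points = 5L) {
  method <- match.arg(method)
  sig <- if (method == "heatflow-log") signal_power(x) else {
    if (!inherits(x, "heat_curve"))
      stop_bad_arg("method 'heat-log' needs a heat_curve")
    list(t = x$time_h, p = x$heat_J)
  }
  if (length(window) != 2L || window[2] <= window[1])
    stop_bad_arg("window must be (t_start, t_end) with t_start < t_end")
  sel <- sig$t >= window[1] & sig$t <= window[2]
  t <- sig$t[sel]; y <- sig$p[sel]
  bad <- y <= 0
  if (any(bad))
    stop("non-positive signal in window at t = ",
         paste(signif(t[bad][seq_len(min(5, sum(bad)))], 5), collapse = ", "),
         " h", call. = FALSE)
  if (length(t) < min_points)
    stop_bad_arg("window contains fewer than ", min_points, " usable points")
  fit <- ols_line(t, log(y))
  phase <- data.frame(t_start = t[1], t_end = t[length(t)], mu = fit$slope,
                      fit_r2 = fit$r2, n_points = length(t))
  class(phase) <- c("growth_phase", "data.frame")
  phase
}

## Plain OLS of y on x with R^2 (0 when y has no variance).
ols_line <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  syy <- sum((y - my)^2)
  sse <- syy - slope * sxy
  r2 <- if (syy > 0) max(0, 1 - sse / syy) else 0
  list(slope = slope, intercept = intercept, r2 = r2, sse = max(sse, 0))
}

#' Resample a heat-flow series onto a new time grid
#'
#' Linear interpolation; extrapolation outside the measured span is
#' refused.
#'
#' @param series A [heatflow_series()].
#' @param grid New time grid (h), inside the series' span.
#' @return A `heatflow_series` on the new grid with the same labels.
#' @export
resample_to_grid <- function(series, grid) {
  stopifnot(inherits(series, "heatflow_series"))
  grid <- as.numeric(grid)
  if (min(grid) < series$time_h[1] - 1e-9 ||
      max(grid) > series$time_h[length(series$time_h)] + 1e-9)
    stop_bad_arg("grid extends beyond the measured time span (",
                 "series '", series$condition, "' passage ", series$passage,
                 " replicate ", series$replicate, ")")
  p <- stats::approx(series$time_h, series$power_W, xout = grid)$y
  heatflow_series(grid, p, replicate = series$replicate,
                  passage = series$passage, condition = series$condition)
}

#' Check the linearity between released heat and biomass
#'
#' Ordinary least-squares fit of final heat against a final biomass proxy
#' (OD or gDW/L) across cultivations; purely diagnostic, no thresholding.
#'
#' @param final_heat_J Numeric vector of total heats (J).
#' @param final_biomass Numeric vector of biomass proxies, same length.
#' @return A list with `slope` (J per biomass unit), `intercept` and `r2`.
#' @export
check_heat_biomass_linearity <- function(final_heat_J, final_biomass) {
  if (length(final_heat_J) != length(final_biomass) || length(final_heat_J) < 3L)
    stop_bad_arg("need >= 3 paired observations")
  fit <- ols_line(final_biomass, final_heat_J)
  list(slope = fit$slope, intercept = fit$intercept, r2 = fit$r2)
}
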