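## Polyphasic growth segmentation: exact dynamic-programming piecewise
## linear regression of ln(heat flow) against time, with the number of
## segments selected by BIC.  Each segment's slope is a phase-specific
## growth rate because heat flow is proportional to the biomass production
## rate.

## All-pairs segment SSE in O(1) per query from cumulative sums.
make_sse_fun <- function(x, y) {
  cx <- c(0, cumsum(x)); cy <- c(0, cumsum(y))
  cxx <- c(0, cumsum(x * x)); cxy <- c(0, cumsum(x * y)); cyy <- c(0, cumsum(y * y))
  function(i, j) {  # vectorized over i for a fixed j
    n <- j - i + 1
    sx <- cx[j + 1] - cx[i]; sy <- cy[j + 1] - cy[i]
    sxx <- cxx[j + 1] - cxx[i] - sx^2 / n
    sxy <- cxy[j + 1] - cxy[i] - sx * sy / n
    syy <- cyy[j + 1] - cyy[i] - sy^2 / n
    sse <- ifelse(sxx > 0, syy - sxy^2 / sxx, syy)
    pmax(sse, 0)
  }
}

## Exact DP over changepoints: best partition of points 1..n into k
## contiguous segments of at least min_len points.  Ties broken towards the
## earliest breakpoints (which.min takes the smallest start index).
dp_segment <- function(sse, n, k_max, min_len) {
  cost <- matrix(Inf, k_max, n)
  from <- matrix(NA_integer_, k_max, n)
  ends <- seq_len(n)
  ok <- which(ends >= min_len)
  cost[1, ok] <- sse(rep(1L, length(ok)), ok)
  if (k_max >= 2) {
    for (k in 2:k_max) {
      for (j in ends) {
        if (j < k * min_len) next
        starts <- seq((k - 1) * min_len + 1L, j - min_len + 1L)
        cand <- cost[k - 1, starts - 1L] + sse(starts, j)
        b <- which.min(cand)
        cost[k, j] <- cand[b]
        from[k, j] <- starts[b]
      }
    }
  }
  list(cost = cost, from = from)
}

backtrack_segments <- function(dp, k, n, min_len) {
  bounds <- integer(0)
  j <- n
  if (k >= 2) for (kk in k:2) {
    i <- dp$from[kk, j]
    bounds <- c(i, bounds)
    j <- i - 1L
  }
  starts <- c(1L, bounds)
  ends <- c(bounds - 1L, n)
  cbind(start = starts, end = ends)
}

## Per-segment OLS refit.  A symmetric edge trim discards the fraction of
## points nearest the changepoints (where Monod transitions bend the log
## signal), and a single MAD-based outlier-trimming pass removes isolated
## points from sharp transitions or the terminal signal collapse.
refit_segment <- function(t, y, min_points, edge_trim = 0.1) {
  n <- length(t)
  drop_n <- floor(edge_trim * n)
  if (n - 2 * drop_n >= min_points && drop_n > 0) {
    keep0 <- (drop_n + 1):(n - drop_n)
    t <- t[keep0]; y <- y[keep0]
  }
  fit <- ols_line(t, y)
  res <- y - (fit$intercept + fit$slope * t)
  thr <- max(3 * stats::mad(res, constant = 1.4826),
             1e-9 + 1e-6 * diff(range(y)))
  keep <- abs(res) <= thr
  if (sum(keep) >= min_points && any(!keep)) fit <- ols_line(t[keep], y[keep])
  else keep <- rep(TRUE, length(t))
  list(fit = fit, n = sum(keep))
}

#' Segment polyphasic growth and estimate phase-specific growth rates
#'
#' Fits an exact changepoint model to `ln(heat flow)` versus time:
#' dynamic programming finds, for every candidate phase count up to
#' `max_phases`, the globally optimal piecewise linear fit, and BIC
#' (penalty `ln(n)` per extra parameter; slope, intercept and breakpoint
#' each count) selects the phase count. Phases shorter than `min_duration`
#' hours are merged into the neighbour that increases the fit error least.
#' Phase slopes are then re-estimated per segment with one MAD-based
#' outlier-trimming pass.
#'
#' Signal preparation: points with non-positive power, or power below
#' `3 * baseline_sd` when a baseline-window noise estimate is available,
#' are excluded from the log fit; the series is truncated after the last
#' point above `rel_floor` of the peak power (terminal starvation collapse
#' is not a growth phase); and `ln(power)` is smoothed with a centered
#' moving median (default width 5) before changepoint search.
#'
#' @param x A [heatflow_series()] or [heat_curve()][baseline_and_integrate].
#' @param max_phases Maximum number of growth phases (>= 1).
#' @param min_points Minimum points per phase.
#' @param min_duration Minimum phase duration (h); shorter phases are
#'   merged.
#' @param smooth_window Width of the moving-median smoother (points).
#' @param noise_floor_W Optional absolute noise floor (W); defaults to
#'   `3 * baseline_sd_W` when `x` is a baseline-corrected heat curve.
#' @param rel_floor Relative tail floor (fraction of the peak power).
#' @param mu_merge_rel Adjacent segments whose slopes differ by less than
#'   this relative amount are merged (a genuine phase change implies a
#'   distinct rate).
#' @param tail_slope_cut Local log-slope (h^-1) below which trailing
#'   points are treated as the terminal starvation collapse and dropped;
#'   growth phases never reach such negative slopes.
#' @param head_slope_cut Local log-slope (h^-1) above which leading points
#'   are treated as the lag-release/instrument warm-up transient and
#'   dropped.
#' @return A data.frame of class `growth_phase`, one row per phase in time
#'   order: `t_start`, `t_end`, `mu` (h^-1), `fit_r2`, `n_points`.
#' @export
segment_phases <- function(x, max_phases = 3L, min_points = 10L,
                           min_duration = 1, smooth_window = 5L,
                           noise_floor_W = NULL, rel_floor = 0.05,
                           mu_merge_rel = 0.05, tail_slope_cut = -1,
                           head_slope_cut = 3) {
  if (max_phases < 1L) stop_bad_arg("max_phases must be >= 1")
  sig <- signal_power(x)
  t <- sig$t; p <- sig$p
  if (is.null(noise_floor_W))
    noise_floor_W <- if (inherits(x, "heat_curve") && x$baseline_sd_W > 0)
      3 * x$baseline_sd_W else 0
  usable <- is.finite(p) & p > pmax(noise_floor_W, 0)
  if (any(usable)) {
    peak <- max(p[usable])
    last_ok <- max(which(usable & p >= rel_floor * peak))
    usable[seq_along(p) > last_ok] <- FALSE
  }
  if (sum(usable) < max(min_points, 3L))
    stop("insufficient positive-signal points for phase segmentation",
         call. = FALSE)
  t <- t[usable]
  y <- smooth_median(log(p[usable]), smooth_window)
  ## transient trimming: the onset (lag release and instrument warm-up)
  ## rises much faster than any growth phase, and the terminal starvation
  ## collapse falls much faster, so leading/trailing runs of extreme local
  ## slope are not phase signal
  n0 <- length(y)
  if (n0 > min_points + 4L) {
    slopes <- c(diff(y) / diff(t), 0)
    cut_hi <- n0
    while (cut_hi > min_points &&
           any(slopes[max(1L, cut_hi - 2L):min(n0 - 1L, cut_hi)] < tail_slope_cut))
      cut_hi <- cut_hi - 1L
    cut_lo <- 1L
    while (cut_lo < cut_hi - min_points &&
           any(slopes[cut_lo:min(cut_lo + 2L, n0 - 1L)] > head_slope_cut))
      cut_lo <- cut_lo + 1L
    if (cut_lo > 1L || cut_hi < n0) {
      t <- t[cut_lo:cut_hi]
      y <- y[cut_lo:cut_hi]
    }
  }
  n <- length(y)
  sse <- make_sse_fun(t, y)
  k_max <- max(1L, min(as.integer(max_phases), n %/% min_points))
  dp <- dp_segment(sse, n, k_max, min_points)
  ## BIC with a small variance floor so that numerically exact fits do not
  ## make the log-likelihood term degenerate
  floor_var <- (1e-6 * max(diff(range(y)), 1))^2
  bic <- vapply(seq_len(k_max), function(k) {
    s <- dp$cost[k, n]
    if (!is.finite(s)) return(Inf)
    n * log((s + n * floor_var) / n) + (3 * k - 1) * log(n)
  }, 0)
  k_best <- which.min(bic)
  seg <- backtrack_segments(dp, k_best, n, min_points)
  ## merge segments shorter than min_duration into the cheaper neighbour
  repeat {
    dur <- t[seg[, "end"]] - t[seg[, "start"]]
    short <- which(dur < min_duration)
    if (length(short) == 0L || nrow(seg) == 1L) break
    i <- short[which.min(dur[short])]
    cand <- c()
    if (i > 1L)
      cand <- c(cand, left = unname(sse(seg[i - 1L, "start"], seg[i, "end"])))
    if (i < nrow(seg))
      cand <- c(cand, right = unname(sse(seg[i, "start"], seg[i + 1L, "end"])))
    if (names(cand)[which.min(cand)] == "left") {
      seg[i - 1L, "end"] <- seg[i, "end"]
    } else {
      seg[i + 1L, "start"] <- seg[i, "start"]
    }
    seg <- seg[-i, , drop = FALSE]
  }
  ## a genuine metabolic phase change implies a distinct rate: merge
  ## adjacent segments whose slopes are within mu_merge_rel of each other
  repeat {
    if (nrow(seg) == 1L) break
    mus <- vapply(seq_len(nrow(seg)), function(i)
      ols_line(t[seg[i, "start"]:seg[i, "end"]],
               y[seg[i, "start"]:seg[i, "end"]])$slope, 0)
    rel <- abs(diff(mus)) / pmax(abs(mus[-1]), abs(mus[-length(mus)]), 1e-12)
    j <- which(rel < mu_merge_rel)
    if (length(j) == 0L) break
    j <- j[1]
    seg[j, "end"] <- seg[j + 1L, "end"]
    seg <- seg[-(j + 1L), , drop = FALSE]
  }
  phases <- do.call(rbind, lapply(seq_len(nrow(seg)), function(i) {
    idx <- seg[i, "start"]:seg[i, "end"]
    rf <- refit_segment(t[idx], y[idx], min_points)
    data.frame(t_start = t[idx[1]], t_end = t[idx[length(idx)]],
               mu = rf$fit$slope, fit_r2 = rf$fit$r2, n_points = rf$n)
  }))
  class(phases) <- c("growth_phase", "data.frame")
  phases
}

#' @export
print.growth_phase <- function(x, ...) {
  cat("<growth_phase>", nrow(x), "phase(s)\n")
  print.data.frame(cbind(x[, c("t_start", "t_end")],
                         mu = signif(x$mu, 4), fit_r2 = signif(x$fit_r2, 4),
                         n_points = x$n_points), row.names = FALSE)
  invisible(x)
}
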