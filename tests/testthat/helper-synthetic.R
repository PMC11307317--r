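# Synthetic inputs built in code: exponential / piecewise-exponential
# heat-flow series, tiny communities, random bounded metabolic networks
# and a brute-force vertex-enumeration LP oracle.

exp_series <- function(mu, A = 2e-6, t = seq(0, 12, by = 0.01), lag = 0,
                       replicate = "r1", passage = 1L, condition = "synthetic") {
  p <- ifelse(t < lag, 0, A * exp(mu * (t - lag)))
  heatflow_series(t, p, replicate = replicate, passage = passage,
                  condition = condition)
}

# Piecewise exponential heat flow: continuous biomass, phase rates `mus`
# switching at `breaks` (h).
piecewise_series <- function(mus, breaks, A = 2e-6, t = seq(0, 16, by = 0.01)) {
  edges <- c(t[1], breaks, t[length(t)] + 1e-9)
  logp <- numeric(length(t))
  offset <- log(A)
  for (i in seq_along(mus)) {
    sel <- t >= edges[i] & t < edges[i + 1]
    logp[sel] <- offset + mus[i] * (t[sel] - edges[i])
    offset <- offset + mus[i] * (edges[i + 1] - edges[i])
  }
  heatflow_series(t, exp(logp), condition = "piecewise")
}

one_strain_params <- function(mu = 0.5, S0 = 50, yield_X = 0.02, K = 0.001,
                              heat_yield = 1500, lag = 0, name = "s1",
                              X0 = 0.001) {
  community_params(
    strains = list(strain_params(name, mu_max = stats::setNames(mu, "S"),
                                 K = c(S = K), yield_X = c(S = yield_X),
                                 heat_yield = heat_yield, lag_h = lag)),
    substrates = c(S = S0),
    initial_biomass = stats::setNames(X0, name))
}

two_disjoint_params <- function(mu1 = 0.5, mu2 = 0.3) {
  community_params(
    strains = list(
      strain_params("s1", mu_max = c(S1 = mu1), K = c(S1 = 0.001),
                    yield_X = c(S1 = 0.02), heat_yield = 1500),
      strain_params("s2", mu_max = c(S2 = mu2), K = c(S2 = 0.001),
                    yield_X = c(S2 = 0.02), heat_yield = 1500)),
    substrates = c(S1 = 20, S2 = 20),
    initial_biomass = c(s1 = 0.001, s2 = 0.001))
}

# Random bounded metabolic network: m internal metabolites, n reactions,
# 0 always feasible (lb <= 0 <= ub), finite box.
random_gem <- function(n = 6, m = 3) {
  repeat {
    S <- matrix(sample(c(-2, -1, -1, 0, 0, 1, 1, 2), m * n, replace = TRUE),
                m, n)
    if (qr(S)$rank == m && all(colSums(S != 0) > 0)) break
  }
  dimnames(S) <- list(paste0("m", seq_len(m)), paste0("r", seq_len(n)))
  lb <- -round(stats::runif(n, 0, 5), 2)
  ub <- round(stats::runif(n, 0.5, 5), 2)
  obj <- numeric(n)
  obj[sample(n, 1)] <- 1
  gem(S, lb, ub, obj, id = "random")
}

# Brute-force LP oracle: enumerate all basic solutions (n - rank(S) bounds
# active at lb or ub), keep feasible ones, return the best objective.
vertex_enum_optimum <- function(model) {
  S <- model$S; lb <- model$lb; ub <- model$ub; obj <- model$obj
  n <- ncol(S); m <- qr(S)$rank
  free <- n - m
  best <- -Inf
  if (free == 0) {
    v <- tryCatch(qr.solve(S, rep(0, nrow(S))), error = function(e) NULL)
    if (!is.null(v) && all(v >= lb - 1e-9 & v <= ub + 1e-9))
      best <- sum(obj * v)
    return(best)
  }
  combs <- utils::combn(n, free)
  for (ci in seq_len(ncol(combs))) {
    fixed <- combs[, ci]
    others <- setdiff(seq_len(n), fixed)
    A <- S[, others, drop = FALSE]
    if (qr(A)$rank < length(others)) next
    for (mask in 0:(2^free - 1)) {
      at_ub <- bitwAnd(mask, 2^(seq_len(free) - 1)) > 0
      vals <- ifelse(at_ub, ub[fixed], lb[fixed])
      x <- tryCatch(qr.solve(A, -S[, fixed, drop = FALSE] %*% vals),
                    error = function(e) NULL)
      if (is.null(x)) next
      v <- numeric(n)
      v[fixed] <- vals; v[others] <- x
      if (all(v >= lb - 1e-9 & v <= ub + 1e-9))
        best <- max(best, sum(obj * v))
    }
  }
  best
}

# Exhaustive changepoint oracle for segmented regression on <= 30 points:
# best SSE over all partitions into k contiguous segments of >= min_len.
exhaustive_seg_sse <- function(t, y, k, min_len) {
  n <- length(t)
  seg_sse <- function(i, j) {
    xs <- t[i:j]; ys <- y[i:j]
    f <- stats::lm.fit(cbind(1, xs), ys)
    sum(f$residuals^2)
  }
  if (k == 1) return(seg_sse(1, n))
  best <- Inf
  recurse <- function(start, k_left, acc) {
    if (k_left == 1) {
      if (n - start + 1 >= min_len) best <<- min(best, acc + seg_sse(start, n))
      return()
    }
    for (end in (start + min_len - 1):(n - (k_left - 1) * min_len)) {
      recurse(end + 1, k_left - 1, acc + seg_sse(start, end))
    }
  }
  recurse(1, k, 0)
  best
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), tol)
}
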