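## Dense two-phase primal simplex with Bland's anti-cycling rule.
##
## Solves  min c'x  s.t.  A_le x <= b_le, A_eq x = b_eq, x >= 0  with all
## right-hand sides non-negative (callers arrange this by flipping rows).
## Slack variables give a starting basis for the inequality rows; phase 1
## drives artificial variables on the equality rows to zero.  Problem
## sizes in this package are tiny (tens of variables), where the dense
## tableau with Bland's rule is exact, deterministic and immune to the
## cycling/NaN failure modes of off-the-shelf educational solvers.

simplex_pivot <- function(T, basis, row, col) {
  T[row, ] <- T[row, ] / T[row, col]
  other <- setdiff(seq_len(nrow(T)), row)
  T[other, ] <- T[other, ] - outer(T[other, col], T[row, ])
  basis[row] <- col
  list(T = T, basis = basis)
}

simplex_phase <- function(T, basis, cost, ncols, tol = 1e-9, max_iter = 10000L) {
  m <- nrow(T)
  rhs <- ncol(T)                                       # rhs is always last
  for (it in seq_len(max_iter)) {
    cb <- cost[basis]
    red <- cost[seq_len(ncols)] - as.numeric(crossprod(cb, T[, seq_len(ncols), drop = FALSE]))
    enter <- which(red < -tol)[1]                      # Bland: smallest index
    if (is.na(enter)) return(list(T = T, basis = basis, status = "optimal"))
    colv <- T[, enter]
    rows <- which(colv > tol)
    if (length(rows) == 0L) return(list(T = T, basis = basis, status = "unbounded"))
    ratio <- T[rows, rhs] / colv[rows]
    best <- rows[ratio <= min(ratio) + tol]
    leave <- best[which.min(basis[best])]              # Bland: smallest basis var
    p <- simplex_pivot(T, basis, leave, enter)
    T <- p$T; basis <- p$basis
  }
  list(T = T, basis = basis, status = "iteration limit")
}

## min c'x, A_le x <= b_le, A_eq x = b_eq, x >= 0, b >= 0.
## Returns list(status, x, value).
simplex_solve <- function(c_vec, A_le = NULL, b_le = NULL,
                          A_eq = NULL, b_eq = NULL, tol = 1e-9) {
  n <- length(c_vec)
  m_le <- if (is.null(A_le)) 0L else nrow(A_le)
  m_eq <- if (is.null(A_eq)) 0L else nrow(A_eq)
  m <- m_le + m_eq
  stopifnot(m > 0)
  if (any(c(b_le, b_eq) < 0)) stop("internal: negative rhs in simplex_solve")
  ncols <- n + m_le + m_eq                      # structural + slack + artificial
  T <- matrix(0, m, ncols + 1L)
  if (m_le > 0) {
    T[seq_len(m_le), seq_len(n)] <- A_le
    T[cbind(seq_len(m_le), n + seq_len(m_le))] <- 1
    T[seq_len(m_le), ncols + 1L] <- b_le
  }
  if (m_eq > 0) {
    r <- m_le + seq_len(m_eq)
    T[r, seq_len(n)] <- A_eq
    T[cbind(r, n + m_le + seq_len(m_eq))] <- 1
    T[r, ncols + 1L] <- b_eq
  }
  basis <- c(n + seq_len(m_le), n + m_le + seq_len(m_eq))
  if (m_eq > 0) {                               # phase 1
    cost1 <- c(rep(0, n + m_le), rep(1, m_eq), 0)
    ph1 <- simplex_phase(T, basis, cost1, ncols, tol)
    if (ph1$status != "optimal") return(list(status = "infeasible", x = NULL,
                                             value = NA_real_))
    T <- ph1$T
    basis <- ph1$basis
    obj1 <- sum(cost1[basis] * T[, ncols + 1L])
    if (obj1 > 1e-7) return(list(status = "infeasible", x = NULL,
                                 value = NA_real_))
    ## pivot any artificial still in the basis out on a structural column
    art <- n + m_le + seq_len(m_eq)
    for (i in which(basis %in% art)) {
      cand <- which(abs(T[i, seq_len(n + m_le)]) > tol)
      if (length(cand)) {
        p <- simplex_pivot(T, basis, i, cand[1])
        T <- p$T; basis <- p$basis
      }
    }
    ## forbid artificials from re-entering
    ncols_use <- n + m_le
  } else {
    ncols_use <- ncols
  }
  cost2 <- c(c_vec, rep(0, ncols - n), 0)
  ph2 <- simplex_phase(T, basis, cost2, ncols_use, tol)
  if (ph2$status == "unbounded")
    return(list(status = "unbounded", x = NULL, value = NA_real_))
  if (ph2$status != "optimal")
    return(list(status = ph2$status, x = NULL, value = NA_real_))
  x <- numeric(ncols)
  x[ph2$basis] <- ph2$T[, ncols + 1L]
  list(status = "optimal", x = x[seq_len(n)],
       value = sum(c_vec * x[seq_len(n)]))
}
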