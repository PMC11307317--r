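#' @keywords internal
"_PACKAGE"

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so that seeded operations do not perturb the global random
#' stream. With `seed = NULL` the expression is evaluated as-is.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (abs(seed) >= 2^31) stop("seed must be below 2^31")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

## Deterministic sub-seed for an operation within a pipeline run, so that a
## single user-facing seed drives independent substreams.  Kept below 2^31.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

## Cumulative trapezoidal integral of y(x); returns vector starting at 0.
cumtrapz <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 2L)
  c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}

## Centered moving median; width must be odd.  Endpoints use shrinking
## windows (stats::runmed with endrule "median").
smooth_median <- function(y, width = 5L) {
  if (width <= 1L || length(y) < width) return(y)
  if (width %% 2L == 0L) width <- width + 1L
  as.numeric(stats::runmed(y, k = width, endrule = "median"))
}

stop_bad_arg <- function(...) stop(..., call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## Named-vector lookup with a default for missing names.  An unnamed
## scalar is recycled to every name.
named_or <- function(x, names, default = 0) {
  out <- rep(default, length(names))
  names(out) <- names
  if (!is.null(x)) {
    x <- unlist(x)
    if (is.null(names(x)) && length(x) == 1L) {
      out[] <- as.numeric(x)
    } else {
      common <- intersect(names(x), names)
      out[common] <- as.numeric(x[common])
    }
  }
  out
}
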