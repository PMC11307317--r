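#' Copy-number-normalized relative abundances from 16S read counts
#'
#' Read counts scale with both biomass and 16S rRNA gene copy number, so
#' each strain's reads are divided by its copy number before computing
#' relative abundances:
#' `fraction_i = (reads_i / c_i) / sum_j (reads_j / c_j)`.
#'
#' @param reads Named or unnamed vector of read counts (>= 0, at least one
#'   positive).
#' @param copy_numbers Vector of 16S copy numbers (>= 1), one per strain.
#' @return Numeric vector of fractions summing to 1.
#' @export
normalize_by_copy_number <- function(reads, copy_numbers) {
  r <- as.numeric(unlist(reads))
  cn <- as.numeric(unlist(copy_numbers))
  if (length(cn) != length(r))
    stop_bad_arg("a copy number is required for every strain")
  if (anyNA(r) || anyNA(cn)) stop_bad_arg("missing reads or copy numbers")
  if (any(r < 0)) stop_bad_arg("read counts must be >= 0")
  if (any(cn < 1)) stop_bad_arg("copy numbers must be >= 1")
  if (sum(r) == 0) stop_bad_arg("all read counts are zero")
  w <- r / cn
  out <- w / sum(w)
  names(out) <- names(reads)
  out
}

#' Abundance table over time from per-strain read counts
#'
#' @param time_h Time of each sampling (h), one value per row.
#' @param strain Strain label per row.
#' @param reads Read count per row.
#' @param copy_numbers Named vector mapping strain to 16S copy number.
#' @return A data.frame of class `abundance_table` with columns `time_h`,
#'   `strain`, `reads`, `copy_number` and the copy-number-normalized
#'   `fraction` (per time point).
#' @export
abundance_table <- function(time_h, strain, reads, copy_numbers) {
  df <- data.frame(time_h = as.numeric(time_h), strain = as.character(strain),
                   reads = as.numeric(reads), stringsAsFactors = FALSE)
  if (any(is.na(match(df$strain, names(copy_numbers)))))
    stop_bad_arg("missing copy number for strain(s): ",
                 paste(setdiff(unique(df$strain), names(copy_numbers)),
                       collapse = ", "))
  df$copy_number <- as.numeric(copy_numbers[df$strain])
  df$fraction <- NA_real_
  for (tp in unique(df$time_h)) {
    i <- df$time_h == tp
    df$fraction[i] <- normalize_by_copy_number(df$reads[i], df$copy_number[i])
  }
  df <- df[order(df$time_h, df$strain), ]
  rownames(df) <- NULL
  class(df) <- c("abundance_table", "data.frame")
  df
}

#' Deconvolve total consortium heat into per-strain heat curves
#'
#' Partitions the cumulative heat of a consortium among strains in
#' proportion to their (optionally weighted) abundance:
#' `Q_i(t) = Q_total(t) * w_i a_i(t) / sum_j w_j a_j(t)`.
#' Abundances are linearly interpolated onto the heat grid and
#' renormalized to the simplex. The per-strain curves sum to the total
#' exactly at every grid point.
#'
#' @param total A `heat_curve` of the whole consortium.
#' @param abundances An [abundance_table()] whose time span covers the heat
#'   grid (no extrapolation).
#' @param heat_weights Optional named per-strain weights (relative heat
#'   yield per gDW); default 1 for all strains.
#' @return Named list of `heat_curve` objects, one per strain.
#' @export
reconstruct_strain_heat <- function(total, abundances, heat_weights = NULL) {
  stopifnot(inherits(total, "heat_curve"))
  strains <- sort(unique(abundances$strain))
  tr <- range(abundances$time_h)
  if (tr[1] > total$time_h[1] + 1e-9 ||
      tr[2] < total$time_h[length(total$time_h)] - 1e-9)
    stop_bad_arg("abundance sampling (", tr[1], "-", tr[2],
                 " h) does not cover the heat grid; refusing to extrapolate")
  w <- named_or(heat_weights, strains, 1)
  shares <- vapply(strains, function(s) {
    a <- abundances[abundances$strain == s, ]
    stats::approx(a$time_h, a$fraction, xout = total$time_h)$y * w[s]
  }, numeric(length(total$time_h)))
  tot <- rowSums(shares)
  tot[tot == 0] <- 1  # no abundance at all: share 0 for everyone
  shares <- shares / tot
  out <- lapply(strains, function(s) {
    structure(list(time_h = total$time_h,
                   heat_J = total$heat_J * shares[, s],
                   power_W = NULL, baseline_W = total$baseline_W,
                   baseline_sd_W = total$baseline_sd_W,
                   replicate = total$replicate, passage = total$passage,
                   condition = paste0(total$condition, ":", s),
                   provenance = "deconvolved from consortium heat by abundance"),
              class = "heat_curve")
  })
  names(out) <- strains
  out
}

#' Growth phases of individual strains inside a consortium
#'
#' Applies phase segmentation to each deconvolved per-strain heat curve.
#' Strains whose curve never rises above zero (abundance zero throughout)
#' yield an empty phase table with a warning.
#'
#' @param strain_curves Named list of `heat_curve`s, e.g. from
#'   [reconstruct_strain_heat()].
#' @param ... Passed to [segment_phases()].
#' @return Named list of `growth_phase` data.frames.
#' @export
strain_growth_rates_in_consortium <- function(strain_curves, ...) {
  out <- lapply(names(strain_curves), function(s) {
    cv <- strain_curves[[s]]
    if (max(cv$heat_J) <= 0) {
      warning("strain '", s, "' has no heat signal; returning no phases",
              call. = FALSE)
      empty <- data.frame(t_start = numeric(0), t_end = numeric(0),
                          mu = numeric(0), fit_r2 = numeric(0),
                          n_points = integer(0))
      class(empty) <- c("growth_phase", "data.frame")
      return(empty)
    }
    segment_phases(cv, ...)
  })
  names(out) <- names(strain_curves)
  out
}
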