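#' Per-replicate endpoint concentration changes
#'
#' Computes `end - start` per (replicate, metabolite) from a long-format
#' metabolite table. Negative deltas are net consumption.
#'
#' @param table Data.frame with columns `sample`, `replicate`,
#'   `metabolite`, `timepoint` ("start"/"end"), `conc_mM`.
#' @return Data.frame with columns `sample`, `replicate`, `metabolite`,
#'   `delta` (mmol/L).
#' @export
delta_by_replicate <- function(table) {
  need <- c("sample", "replicate", "metabolite", "timepoint", "conc_mM")
  if (!all(need %in% names(table)))
    stop_bad_arg("metabolite table needs columns: ", paste(need, collapse = ", "))
  s <- table[table$timepoint == "start", ]
  e <- table[table$timepoint == "end", ]
  key <- function(d) paste(d$sample, d$replicate, d$metabolite, sep = "\r")
  i <- match(key(e), key(s))
  if (anyNA(i)) {
    miss <- e[is.na(i), ]
    stop("missing start concentration for ",
         paste(sprintf("%s/%s (replicate %s)", miss$sample, miss$metabolite,
                       miss$replicate)[seq_len(min(5, nrow(miss)))],
               collapse = "; "), call. = FALSE)
  }
  orphan <- !(key(s) %in% key(e))
  if (any(orphan)) {
    miss <- s[orphan, ][1, ]
    stop("missing end concentration for ", miss$sample, "/", miss$metabolite,
         " (replicate ", miss$replicate, ")", call. = FALSE)
  }
  out <- data.frame(sample = e$sample, replicate = e$replicate,
                    metabolite = e$metabolite,
                    delta = e$conc_mM - s$conc_mM[i],
                    stringsAsFactors = FALSE)
  out[order(out$metabolite, out$replicate), ]
}

#' Mean and SD of endpoint concentration changes across replicates
#'
#' @inheritParams delta_by_replicate
#' @return Data.frame with `metabolite`, `mean_delta`, `sd_delta`
#'   (NA when n < 2) and `n`.
#' @export
concentration_deltas <- function(table) {
  d <- delta_by_replicate(table)
  agg <- lapply(split(d$delta, d$metabolite), function(v) {
    c(mean(v), if (length(v) >= 2) stats::sd(v) else NA_real_, length(v))
  })
  out <- data.frame(metabolite = names(agg),
                    mean_delta = vapply(agg, `[`, 0, 1),
                    sd_delta = vapply(agg, `[`, 0, 2),
                    n = as.integer(vapply(agg, `[`, 0, 3)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

## Two-sided equal-variance two-sample t statistic with explicit handling
## of the zero-variance degenerate cases (identical groups -> t = 0,
## p = 1; constant but different groups -> p reported as 0 and flagged).
student_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  diff <- mean(a) - mean(b)
  if (sp2 <= 0) {
    if (abs(diff) <= .Machine$double.eps * 100)
      return(list(t = 0, p = 1, df = na + nb - 2, degenerate = FALSE))
    return(list(t = sign(diff) * Inf, p = 0, df = na + nb - 2,
                degenerate = TRUE))
  }
  t <- diff / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * stats::pt(-abs(t), df = na + nb - 2),
       df = na + nb - 2, degenerate = FALSE)
}

p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Compare consortium metabolite production against stacked monocultures
#'
#' The expected "no interaction" concentration change of the consortium is
#' the sum of the monoculture changes. Monoculture replicate deltas are
#' stacked by replicate index (replicate r of the stack is the sum over
#' strains of their replicate-r delta), preserving replicate variance, and
#' compared to the consortium replicate deltas with a two-sided
#' equal-variance Student's t-test. Stars encode p < 0.05 (*), < 0.01 (**)
#' and < 0.001 (***).
#'
#' @param mono_tables Named list of monoculture metabolite tables (one per
#'   strain), each as in [delta_by_replicate()].
#' @param consortium_table Consortium metabolite table.
#' @param p_adjust Multiple-testing correction across metabolites:
#'   `"none"` (default, raw p-values as stars) or `"BH"`.
#' @return Data.frame with per-metabolite consortium and stacked means,
#'   SDs, `t`, `p`, `stars` and a `degenerate` flag for zero-variance
#'   comparisons.
#' @export
compare_consortium_vs_stack <- function(mono_tables, consortium_table,
                                        p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  cons <- delta_by_replicate(consortium_table)
  monos <- lapply(mono_tables, delta_by_replicate)
  mets <- sort(unique(cons$metabolite))
  reps <- sort(unique(cons$replicate))
  for (m in names(monos)) {
    r <- sort(unique(monos[[m]]$replicate))
    if (length(r) != length(reps))
      stop_bad_arg("unequal replicate counts: consortium has ", length(reps),
                   ", monoculture '", m, "' has ", length(r))
  }
  rows <- lapply(mets, function(met) {
    cv <- cons$delta[cons$metabolite == met][order(cons$replicate[cons$metabolite == met])]
    stack <- rowSums(vapply(monos, function(d) {
      x <- d[d$metabolite == met, ]
      if (nrow(x) == 0) return(rep(0, length(reps)))
      x$delta[order(x$replicate)]
    }, numeric(length(reps))))
    tt <- student_t(cv, stack)
    data.frame(metabolite = met, consortium_mean = mean(cv),
               consortium_sd = stats::sd(cv), stacked_mean = mean(stack),
               stacked_sd = stats::sd(stack), t = tt$t, p = tt$p,
               degenerate = tt$degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  p_use <- if (p_adjust == "BH") stats::p.adjust(out$p, "BH") else out$p
  out$p_adj <- p_use
  out$stars <- p_stars(p_use)
  out
}

#' Convert a concentration change into a specific exchange rate
#'
#' The endpoint concentration difference is expressed per gram dry weight
#' and multiplied by the growth rate, assuming the change accumulated
#' before stationary phase: `q = (delta / biomass) * mu`
#' in mmol per gDW per hour. Negative rates are consumption.
#'
#' @param delta Concentration change (mmol/L), scalar or vector.
#' @param biomass Biomass concentration (gDW/L), > 0.
#' @param mu Specific growth rate (h^-1), >= 0.
#' @param sd Optional SD of `delta`, scaled identically.
#' @return Data.frame with `rate` (mmol/gDW/h) and `sd`.
#' @export
exchange_rate <- function(delta, biomass, mu, sd = NA_real_) {
  if (any(biomass <= 0)) stop_bad_arg("biomass must be > 0")
  if (any(mu < 0)) stop_bad_arg("mu must be >= 0")
  data.frame(rate = delta / biomass * mu, sd = sd / biomass * mu)
}

#' Convert an optical density to a dry-weight concentration
#'
#' @param od Optical density at 600 nm.
#' @param factor Conversion factor (gDW/L per OD600 unit), default 0.4.
#' @return Biomass in gDW/L.
#' @export
od_to_gdw <- function(od, factor = 0.4) od * factor

#' PCA of endpoint amino-acid (or metabolite) profiles
#'
#' Builds a samples-by-metabolites matrix from endpoint concentrations
#' (including any blank-medium reference rows) and delegates to the
#' centered, scaled PCA core.
#'
#' @param tables List of metabolite tables (long format, as in
#'   [delta_by_replicate()]); only `timepoint == "end"` rows are used,
#'   except for samples that carry a single timepoint (such as a blank
#'   medium reference), which are used as-is.
#' @param n_components Number of components.
#' @return A `heat_pca` with one row per (sample, replicate).
#' @export
amino_acid_profile_pca <- function(tables, n_components = 2L) {
  long <- do.call(rbind, lapply(tables, function(tb) {
    tps <- unique(tb$timepoint)
    if ("end" %in% tps && length(tps) > 1L) tb[tb$timepoint == "end", ] else tb
  }))
  mets <- sort(unique(long$metabolite))
  bad <- vapply(split(long$metabolite, paste(long$sample, long$replicate)),
                function(m) !setequal(m, mets), TRUE)
  if (any(bad))
    stop_bad_arg("metabolite sets differ between samples: ",
                 paste(names(bad)[bad][seq_len(min(3, sum(bad)))], collapse = ", "))
  ids <- unique(long[, c("sample", "replicate")])
  m <- t(vapply(seq_len(nrow(ids)), function(i) {
    x <- long[long$sample == ids$sample[i] & long$replicate == ids$replicate[i], ]
    x$conc_mM[match(mets, x$metabolite)]
  }, numeric(length(mets))))
  rownames(m) <- paste(ids$sample, ids$replicate, sep = "_")
  colnames(m) <- mets
  pca <- pca_scores(m, center = TRUE, scale. = TRUE,
                    n_components = n_components)
  pca$sample <- ids$sample
  pca$replicate <- ids$replicate
  pca
}
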