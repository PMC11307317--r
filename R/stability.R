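#' Assemble heat-flow series into a passage-by-time matrix
#'
#' Resamples every ampoule's heat flow onto a common grid and stacks them
#' as rows, canonically ordered by (passage, replicate), ready for PCA.
#'
#' @param series_list List of [heatflow_series()].
#' @param grid Common time grid (h); must lie inside every series' span.
#' @return A numeric matrix of class `passage_matrix` (rows = ampoules,
#'   columns = grid times) with attributes `passage` and `replicate`.
#' @export
assemble_passage_matrix <- function(series_list, grid) {
  stopifnot(length(series_list) >= 1L)
  res <- lapply(series_list, resample_to_grid, grid = grid)
  passage <- vapply(res, `[[`, 1L, "passage")
  replicate <- vapply(res, `[[`, "", "replicate")
  ord <- order(passage, replicate)
  m <- do.call(rbind, lapply(res[ord], `[[`, "power_W"))
  rownames(m) <- sprintf("p%d_%s", passage[ord], replicate[ord])
  colnames(m) <- signif(grid, 8)
  structure(m, passage = passage[ord], replicate = replicate[ord],
            class = c("passage_matrix", "matrix", "array"))
}

#' Principal component scores of heat-flow (or profile) matrices
#'
#' Singular value decomposition of the centered (and by default
#' unit-variance-scaled) data. Zero-variance columns are dropped before
#' scaling, where unit-variance scaling is undefined. The sign of each
#' component is fixed so that its largest-magnitude loading is positive.
#'
#' @param mat Numeric matrix, rows = samples (>= 2).
#' @param center,scale. Center/scale columns before decomposition.
#' @param n_components Number of components to retain.
#' @return An object of class `heat_pca`: `scores`, `loadings`,
#'   `explained_variance` (ratios), `center`, `scale`, `kept_columns`,
#'   row labels (`passage`, `replicate` when present) and a `no_variance`
#'   flag for degenerate input.
#' @export
pca_scores <- function(mat, center = TRUE, scale. = TRUE, n_components = 2L) {
  m <- unclass(mat)
  if (nrow(m) < 2L) stop_bad_arg("PCA needs at least 2 rows")
  v <- apply(m, 2, stats::var)
  keep <- which(v > max(v) * 1e-12)   # relative: data magnitude is arbitrary
  no_variance <- max(v) == 0 || length(keep) == 0L
  n_components <- max(1L, as.integer(n_components))
  if (no_variance) {
    k <- n_components
    sc <- matrix(0, nrow(m), k,
                 dimnames = list(rownames(m), paste0("PC", seq_len(k))))
    return(structure(list(scores = sc, loadings = NULL,
                          explained_variance = rep(0, k),
                          center = colMeans(m), scale = NULL,
                          kept_columns = integer(0), no_variance = TRUE,
                          passage = attr(mat, "passage"),
                          replicate = attr(mat, "replicate")),
                     class = "heat_pca"))
  }
  mk <- m[, keep, drop = FALSE]
  ctr <- if (center) colMeans(mk) else rep(0, ncol(mk))
  scl <- if (scale.) apply(mk, 2, stats::sd) else rep(1, ncol(mk))
  z <- sweep(sweep(mk, 2, ctr), 2, scl, `/`)
  sv <- svd(z)
  k <- min(n_components, length(sv$d))
  load <- sv$v[, seq_len(k), drop = FALSE]
  ## sign convention: largest-magnitude loading positive
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE], 2, sv$d[seq_len(k)], `*`)
  dimnames(scores) <- list(rownames(m), paste0("PC", seq_len(k)))
  rownames(load) <- colnames(mk)
  colnames(load) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = load,
                 explained_variance = (sv$d^2 / sum(sv$d^2))[seq_len(k)],
                 center = ctr, scale = scl, kept_columns = keep,
                 no_variance = FALSE,
                 passage = attr(mat, "passage"),
                 replicate = attr(mat, "replicate")),
            class = "heat_pca")
}

#' @export
print.heat_pca <- function(x, ...) {
  cat("<heat_pca>", nrow(x$scores), "samples,", ncol(x$scores), "components")
  if (x$no_variance) cat(" [no variance]")
  cat("\n  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "), "\n")
  invisible(x)
}

#' Project new rows into an existing PCA
#'
#' @param pca A `heat_pca` fitted on reference data.
#' @param mat New matrix with the same columns as the reference.
#' @return Score matrix of the new rows.
#' @export
project_pca <- function(pca, mat) {
  if (pca$no_variance) stop_bad_arg("cannot project onto a no-variance PCA")
  m <- unclass(mat)[, pca$kept_columns, drop = FALSE]
  z <- sweep(sweep(m, 2, pca$center), 2, pca$scale, `/`)
  sc <- z %*% pca$loadings
  rownames(sc) <- rownames(mat)
  sc
}

## Pooled mean replicate-to-centroid distance and per-passage centroids in
## the leading PC plane.
passage_centroids <- function(scores, passage, n_use = 2L) {
  n_use <- min(n_use, ncol(scores))
  s <- scores[, seq_len(n_use), drop = FALSE]
  pl <- sort(unique(passage))
  cen <- t(vapply(pl, function(p) colMeans(s[passage == p, , drop = FALSE]),
                  numeric(n_use)))
  rownames(cen) <- pl
  dists <- unlist(lapply(seq_along(pl), function(i) {
    rows <- s[passage == pl[i], , drop = FALSE]
    sqrt(rowSums(sweep(rows, 2, cen[i, ])^2))
  }))
  list(passages = pl, centroids = cen, d_w = mean(dists))
}

#' Detect the passage at which growth kinetics become stable
#'
#' Stability is reproducibility of the heat-flow curve between consecutive
#' passages. In the plane of the first two principal components, the
#' within-passage dispersion `d_w` (pooled mean replicate-to-centroid
#' distance) sets the natural scale of replicate noise; the stability
#' passage is the first passage from which every subsequent
#' consecutive-passage centroid shift stays within `k * d_w`.
#'
#' @param pca A `heat_pca` carrying `passage`/`replicate` labels, or a
#'   score matrix (then `passage` must be given).
#' @param passage Optional passage index per row (overrides labels in
#'   `pca`).
#' @param k Threshold multiplier on `d_w`. The default 4 places the
#'   threshold about three standard errors of a triplicate
#'   centroid difference above the pure-noise level.
#' @param n_components Number of leading components used (default 2).
#' @return A list of class `stability_report`: `passages_to_stability`
#'   (NA when never reached), `reached`, per-passage `centroids`,
#'   consecutive `shifts`, `d_w`, `threshold` and `k`.
#' @export
detect_stable_passage <- function(pca, passage = NULL, k = 4,
                                  n_components = 2L) {
  scores <- if (inherits(pca, "heat_pca")) pca$scores else as.matrix(pca)
  if (is.null(passage))
    passage <- if (inherits(pca, "heat_pca")) pca$passage else NULL
  if (is.null(passage)) stop_bad_arg("passage labels are required")
  if (length(unique(passage)) < 2L) stop_bad_arg("need >= 2 passages")
  if (min(table(passage)) < 2L)
    stop_bad_arg("need >= 2 replicates per passage")
  pc <- passage_centroids(scores, passage, n_components)
  np <- length(pc$passages)
  shifts <- sqrt(rowSums((pc$centroids[-1, , drop = FALSE] -
                          pc$centroids[-np, , drop = FALSE])^2))
  names(shifts) <- sprintf("%d-%d", pc$passages[-np], pc$passages[-1])
  thr <- k * pc$d_w
  ok <- shifts <= thr
  stab <- NA_integer_
  for (p in seq_len(np - 1L)) {
    if (all(ok[p:(np - 1L)])) { stab <- pc$passages[p]; break }
  }
  structure(list(passages_to_stability = stab, reached = !is.na(stab),
                 centroids = pc$centroids, shifts = shifts, d_w = pc$d_w,
                 threshold = thr, k = k), class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report> d_w =", signif(x$d_w, 4),
      " threshold =", signif(x$threshold, 4), "(k =", x$k, ")\n")
  if (x$reached)
    cat("  stability reached at passage", x$passages_to_stability, "\n")
  else cat("  stability not reached\n")
  cat("  consecutive centroid shifts:\n")
  print(signif(x$shifts, 4))
  invisible(x)
}

#' Assess resilience of a perturbed consortium against a stable reference
#'
#' Perturbed heat-flow curves are projected into the reference PCA. The
#' kinetic recovery passage is the first passage whose centroid lies
#' within `k * d_w(reference)` of the reference stable-region centroid
#' (the mean score over all reference passages at or after the reference
#' stability passage). Composition recovery is assessed separately with
#' [composition_recovery()].
#'
#' @param perturbed A `passage_matrix` of the perturbed run (same grid as
#'   the reference matrix).
#' @param reference_pca The `heat_pca` of the reference run. Distances are
#'   measured in its full retained score space: fitting the reference with
#'   several components (e.g. 10) makes the comparison insensitive to how
#'   replicate noise rotates the leading axes, while a 2-component
#'   reference reproduces the planar view.
#' @param reference_report The reference [detect_stable_passage()] report.
#' @param k Threshold multiplier; defaults to the reference report's `k`.
#'   The within-passage dispersion `d_w` entering the threshold is
#'   recomputed in the same score space as the distances.
#' @return List of class `resilience_report`: `recovery_passage` (NA when
#'   never recovered), `recovered`, per-passage `distances`, `threshold`.
#' @export
assess_resilience <- function(perturbed, reference_pca, reference_report,
                              k = reference_report$k) {
  if (!reference_report$reached)
    stop_bad_arg("reference run never reached stability")
  scores <- project_pca(reference_pca, perturbed)
  n_use <- ncol(scores)
  ref_all <- passage_centroids(reference_pca$scores, reference_pca$passage,
                               n_use)
  ref_scores <- reference_pca$scores[, seq_len(n_use), drop = FALSE]
  stable_rows <- reference_pca$passage >= reference_report$passages_to_stability
  stable_centroid <- colMeans(ref_scores[stable_rows, , drop = FALSE])
  pc <- passage_centroids(scores, attr(perturbed, "passage"), n_use)
  d <- sqrt(rowSums(sweep(pc$centroids, 2, stable_centroid)^2))
  names(d) <- pc$passages
  thr <- k * ref_all$d_w
  rec <- pc$passages[which(d <= thr)[1]]
  structure(list(recovery_passage = if (length(rec) && !is.na(rec)) rec else NA_integer_,
                 recovered = any(d <= thr), distances = d, threshold = thr,
                 k = k), class = "resilience_report")
}

#' @export
print.resilience_report <- function(x, ...) {
  cat("<resilience_report> threshold =", signif(x$threshold, 4), "\n")
  if (x$recovered) cat("  kinetics recovered at passage", x$recovery_passage, "\n")
  else cat("  kinetics not recovered\n")
  print(signif(x$distances, 4))
  invisible(x)
}

#' Composition recovery passage after a perturbation
#'
#' @param fractions Data.frame with columns `passage`, `strain`,
#'   `fraction` for the perturbed run (end-of-passage composition).
#' @param reference Named numeric vector, the reference stable composition.
#' @param tol Maximum absolute per-strain deviation (default 0.05).
#' @return List with `recovery_passage` (NA if never), `recovered` and the
#'   per-passage maximum absolute deviation `max_dev`.
#' @export
composition_recovery <- function(fractions, reference, tol = 0.05) {
  pl <- sort(unique(fractions$passage))
  dev <- vapply(pl, function(p) {
    f <- fractions[fractions$passage == p, ]
    max(abs(f$fraction - reference[f$strain]))
  }, 0)
  names(dev) <- pl
  rec <- pl[which(dev <= tol)[1]]
  list(recovery_passage = if (length(rec) && !is.na(rec)) rec else NA_integer_,
       recovered = any(dev <= tol), max_dev = dev, tol = tol)
}
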