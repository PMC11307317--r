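make_curve <- function(shift, noise, seed, passage, replicate,
                       t = seq(0, 10, by = 0.1)) {
  set.seed(seed)
  p <- 1e-6 * exp(-(t - 4 - shift)^2) + stats::rnorm(length(t), 0, noise)
  heatflow_series(t, p, replicate = replicate, passage = passage,
                  condition = "syn")
}

drifted_set <- function(shifts, noise = 1e-9, reps = 3) {
  out <- list()
  seed <- 0
  for (p in seq_along(shifts)) for (r in seq_len(reps)) {
    seed <- seed + 1
    out[[length(out) + 1]] <- make_curve(shifts[p], noise, seed, p,
                                         sprintf("r%d", r))
  }
  out
}

test_that("passage matrices are canonically ordered and resampled to the grid", {
  series <- drifted_set(c(0, 0, 0))
  grid <- seq(1, 9, by = 0.5)
  m <- assemble_passage_matrix(series, grid)
  expect_identical(dim(m), c(9L, length(grid)))
  expect_identical(rownames(m)[1:3], c("p1_r1", "p1_r2", "p1_r3"))
  shuffled <- assemble_passage_matrix(rev(series), grid)
  expect_equal(unclass(m), unclass(shuffled))
  one <- assemble_passage_matrix(series[1], grid)
  expect_identical(nrow(one), 1L)
  short <- heatflow_series(seq(2, 5, 0.5), rep(1e-6, 7), condition = "short")
  expect_error(assemble_passage_matrix(c(series, list(short)), grid), "short")
})

test_that("PCA scores reproduce standard geometry", {
  m <- rbind(c(1, 0), c(-1, 0), c(1, 0.001), c(-1, -0.001))
  pca <- pca_scores(m, center = TRUE, scale. = FALSE)
  expect_gt(pca$explained_variance[1], 0.999)
  # two identical rows -> equal scores
  m2 <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(4, 0, 3))
  p2 <- pca_scores(m2, scale. = FALSE)
  expect_equal(p2$scores["a", ], p2$scores["b", ])
  # no variance at all is flagged, not an error
  p3 <- pca_scores(rbind(c(1, 1), c(1, 1)))
  expect_true(p3$no_variance)
  expect_error(pca_scores(matrix(1, 1, 3)), "2 rows")
})

test_that("full-rank scores reconstruct the centered scaled data", {
  set.seed(21)
  m <- matrix(stats::rnorm(21 * 40), 21, 40)
  pca <- pca_scores(m, n_components = 21)
  z <- scale(m, center = pca$center, scale = pca$scale)
  recon <- pca$scores %*% t(pca$loadings)
  expect_lt(max(abs(recon - z)), 1e-8)
  # distances in full score space equal distances in the scaled data
  d1 <- stats::dist(pca$scores)
  d2 <- stats::dist(z)
  expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 1e-8)
})

test_that("projection of the training rows matches their scores", {
  set.seed(22)
  m <- matrix(stats::rnorm(12 * 30), 12, 30)
  pca <- pca_scores(m, n_components = 2)
  proj <- project_pca(pca, m)
  expect_equal(unname(proj), unname(pca$scores), tolerance = 1e-8)
})

test_that("identical passages are stable from the first passage", {
  series <- drifted_set(rep(0, 5), noise = 1e-9)
  m <- assemble_passage_matrix(series, seq(0.5, 9.5, by = 0.1))
  rep <- detect_stable_passage(pca_scores(m, scale. = FALSE), k = 4)
  expect_true(rep$reached)
  expect_identical(rep$passages_to_stability, 1L)
})

test_that("monotone never-converging drift is flagged as not reached", {
  series <- drifted_set(c(0, 1, 2, 3, 4), noise = 1e-9)
  m <- assemble_passage_matrix(series, seq(0.5, 9.5, by = 0.1))
  rep <- detect_stable_passage(pca_scores(m, scale. = FALSE), k = 4)
  expect_false(rep$reached)
  expect_true(is.na(rep$passages_to_stability))
})

test_that("a drift schedule converging mid-series is detected at the designed passage", {
  # geometric curve shifts 0.5, 0.05, 0.005, ...; the noise level places
  # the detection threshold between the passage 2-3 and 3-4 centroid shifts
  series <- drifted_set(0.5 * 0.1^(0:4), noise = 4e-9)
  m <- assemble_passage_matrix(series, seq(0.5, 9.5, by = 0.1))
  pca <- pca_scores(m, scale. = FALSE)
  rep3 <- detect_stable_passage(pca, k = 4)
  expect_identical(rep3$passages_to_stability, 3L)
})

test_that("the stability passage is monotone in the threshold multiplier", {
  series <- drifted_set(0.4 * 0.3^(0:4), noise = 1e-9)
  m <- assemble_passage_matrix(series, seq(0.5, 9.5, by = 0.1))
  pca <- pca_scores(m, scale. = FALSE)
  ks <- c(0.5, 1, 2, 4, 8, 16)
  stab <- vapply(ks, function(k) {
    r <- detect_stable_passage(pca, k = k)
    if (r$reached) r$passages_to_stability else length(unique(pca$passage)) + 1L
  }, 1L)
  expect_true(all(diff(stab) <= 0))
})

test_that("an unperturbed run projected on its own reference recovers immediately", {
  series <- drifted_set(rep(0, 4), noise = 1e-9)
  grid <- seq(0.5, 9.5, by = 0.1)
  m <- assemble_passage_matrix(series, grid)
  pca <- pca_scores(m, scale. = FALSE)
  rep <- detect_stable_passage(pca, k = 4)
  res <- assess_resilience(m, pca, rep)
  expect_true(res$recovered)
  expect_identical(res$recovery_passage, 1L)
})

test_that("composition recovery reports the first passage within tolerance", {
  fr <- data.frame(passage = rep(1:3, each = 2),
                   strain = rep(c("a", "b"), 3),
                   fraction = c(0.9, 0.1, 0.62, 0.38, 0.61, 0.39))
  ref <- c(a = 0.6, b = 0.4)
  out <- composition_recovery(fr, ref, tol = 0.05)
  expect_identical(out$recovery_passage, 2L)
  out2 <- composition_recovery(fr[fr$passage == 1, ], ref, tol = 0.05)
  expect_false(out2$recovered)
})
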