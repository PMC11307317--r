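make_table <- function(sample, deltas_by_rep, start = 1) {
  # deltas_by_rep: list metabolite -> numeric vector (one delta per replicate)
  rows <- list()
  for (met in names(deltas_by_rep)) {
    d <- deltas_by_rep[[met]]
    for (r in seq_along(d)) {
      rows[[length(rows) + 1]] <- data.frame(
        sample = sample, replicate = r, metabolite = met,
        timepoint = c("start", "end"), conc_mM = c(start, start + d[r]))
    }
  }
  do.call(rbind, rows)
}

test_that("concentration deltas compute end minus start with replicate statistics", {
  tab <- make_table("x", list(ace = c(2, 2, 2), mal = c(-1, -1, -1)))
  d <- concentration_deltas(tab)
  expect_equal(d$mean_delta[d$metabolite == "ace"], 2)
  expect_equal(d$sd_delta[d$metabolite == "ace"], 0)
  expect_equal(d$mean_delta[d$metabolite == "mal"], -1)
  tab2 <- make_table("x", list(but = c(2.0, 2.2, 1.8)))
  d2 <- concentration_deltas(tab2)
  expect_equal(d2$mean_delta, 2.0)
  expect_equal(d2$sd_delta, 0.2)
  broken <- tab[tab$timepoint == "end" | tab$metabolite == "mal", ]
  expect_error(concentration_deltas(broken), "missing start")
})

test_that("consortium-versus-stack comparison reproduces the closed-form t-test", {
  mono <- list(s1 = make_table("s1", list(ace = c(1.0, 1.2, 0.8))),
               s2 = make_table("s2", list(ace = c(2.0, 2.1, 1.9))))
  cons <- make_table("cons", list(ace = c(4.4, 4.6, 4.5)))
  out <- compare_consortium_vs_stack(mono, cons)
  # stacked replicates: (3.0, 3.3, 2.7); cross-check against stats::t.test
  tt <- stats::t.test(c(4.4, 4.6, 4.5), c(3.0, 3.3, 2.7), var.equal = TRUE)
  expect_equal(out$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(out$p, tt$p.value, tolerance = 1e-12)
  expect_equal(out$stacked_mean, 3.0)
})

test_that("identical groups give t = 0, p = 1 and no star; constant different groups are flagged", {
  mono <- list(s1 = make_table("s1", list(ace = c(5, 5, 5))))
  cons_same <- make_table("cons", list(ace = c(5, 5, 5)))
  out <- compare_consortium_vs_stack(mono, cons_same)
  expect_equal(out$t, 0)
  expect_equal(out$p, 1)
  expect_identical(out$stars, "")
  cons_diff <- make_table("cons", list(ace = c(10, 10, 10)))
  out2 <- compare_consortium_vs_stack(mono, cons_diff)
  expect_true(out2$degenerate)
  expect_equal(out2$p, 0)
})

test_that("swapping the groups negates t and preserves p", {
  a <- c(4.4, 4.6, 4.5); b <- c(3.0, 3.3, 2.7)
  t1 <- calorimix:::student_t(a, b)
  t2 <- calorimix:::student_t(b, a)
  expect_equal(t1$t, -t2$t)
  expect_equal(t1$p, t2$p)
})

test_that("significance stars follow the conventional thresholds", {
  expect_identical(calorimix:::p_stars(c(0.2, 0.04, 0.004, 0.0004)),
                   c("", "*", "**", "***"))
})

test_that("unequal replicate counts are refused rather than silently truncated", {
  mono <- list(s1 = make_table("s1", list(ace = c(1, 1))))
  cons <- make_table("cons", list(ace = c(1, 1, 1)))
  expect_error(compare_consortium_vs_stack(mono, cons), "unequal replicate")
})

test_that("stacking one strain equals that strain's deltas", {
  mono <- list(s1 = make_table("s1", list(ace = c(1.1, 0.9, 1.0))))
  cons <- make_table("cons", list(ace = c(1.1, 0.9, 1.0)))
  out <- compare_consortium_vs_stack(mono, cons)
  expect_equal(out$stacked_mean, out$consortium_mean)
  expect_equal(out$t, 0)
})

test_that("exchange rates scale as delta over biomass times growth rate", {
  q <- exchange_rate(10, biomass = 1, mu = 0.5, sd = 2)
  expect_equal(q$rate, 5)
  expect_equal(q$sd, 1)
  expect_equal(exchange_rate(0, 1, 0.5)$rate, 0)
  expect_equal(exchange_rate(10, 1, 1.0)$rate, 2 * exchange_rate(10, 1, 0.5)$rate)
  expect_equal(exchange_rate(10, 2, 0.5)$rate, exchange_rate(10, 1, 0.5)$rate / 2)
  expect_error(exchange_rate(1, 0, 0.5), "biomass")
  expect_equal(od_to_gdw(2.5), 1.0)
})

test_that("amino-acid profile PCA separates a constructed contrast and keeps identical samples together", {
  aas <- paste0("aa", 1:10)
  ref_conc <- rep(2, 10)
  mk <- function(sample, conc, seed, n = 3, jit = 0.01) {
    set.seed(seed)
    do.call(rbind, lapply(seq_len(n), function(r)
      data.frame(sample = sample, replicate = r, metabolite = aas,
                 timepoint = "end",
                 conc_mM = conc + stats::rnorm(length(aas), 0, jit))))
  }
  shifted <- ref_conc + c(rep(3, 5), rep(0, 5))  # offset on half the amino acids
  tables <- list(mk("ref", ref_conc, seed = 41), mk("shifted", shifted, seed = 42),
                 mk("ref2", ref_conc, seed = 41))
  pca <- amino_acid_profile_pca(tables)
  pc1 <- pca$scores[, 1]
  sep <- abs(mean(pc1[pca$sample == "shifted"]) -
             mean(pc1[pca$sample %in% c("ref", "ref2")]))
  spread <- stats::sd(pc1[pca$sample %in% c("ref", "ref2")])
  expect_gt(sep, 5 * spread)
  # identical samples sit at (almost) coincident scores
  expect_lt(max(abs(pca$scores[pca$sample == "ref", 1] -
                    pca$scores[pca$sample == "ref2", 1])), 1e-6)
  bad <- tables
  bad[[2]] <- bad[[2]][bad[[2]]$metabolite != "aa1", ]
  expect_error(amino_acid_profile_pca(bad), "differ")
})
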