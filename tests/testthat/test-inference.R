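test_that("bootstrap p-value follows the add-one convention with strict exceedance", {
  # 73 exceedances out of 999 -> (1+73)/(1+999)
  tau_star <- c(rep(2, 73), rep(0, 926))
  expect_equal(bootstrap_pvalue(1, tau_star), 0.074)
  expect_equal(bootstrap_pvalue(1, rep(0, 999)), 0.001)   # floor 1/(R+1)
  expect_equal(bootstrap_pvalue(1, rep(2, 999)), 1)       # ceiling
  # ties are not exceedances (strict inequality)
  expect_equal(bootstrap_pvalue(1, rep(1, 9)), 0.1)
  expect_error(bootstrap_pvalue(1, numeric(0)), "nonempty")
})

test_that("p-value bounds and monotonicity in the number of exceedances hold", {
  set.seed(3)
  for (i in 1:50) {
    R <- sample(5:500, 1)
    ts <- rnorm(R)
    p <- bootstrap_pvalue(rnorm(1), ts)
    expect_gte(p, 1 / (R + 1))
    expect_lte(p, 1)
  }
  base <- rep(0, 99)
  p_prev <- -Inf
  for (ex in c(0, 5, 50, 99)) {
    ts <- c(rep(2, ex), rep(0, 99 - ex))
    p <- bootstrap_pvalue(1, ts)
    expect_gt(p, p_prev)
    p_prev <- p
  }
})

test_that("percentile interval uses the stated order-statistic indices", {
  # R*alpha non-integer: k = floor((R+1)*alpha) -> 25th and 975th at R = 999
  expect_equal(unname(percentile_ci(1:999, alpha = 0.025)), c(25, 975))
  # R*alpha integer: direct indices
  expect_equal(unname(percentile_ci(1:1000, alpha = 0.025)), c(25, 975))
  expect_equal(unname(percentile_ci(1:9, alpha = 0.1)), c(1, 9))
  # degenerate distribution collapses the interval
  expect_equal(unname(percentile_ci(rep(4, 99), alpha = 0.025)), c(4, 4))
  expect_error(percentile_ci(1:999, alpha = 0.6), "alpha")
  expect_error(percentile_ci(1:5, alpha = 0.025), "too few replicates")
})

test_that("percentile interval matches naive sort-and-index on random vectors", {
  set.seed(17)
  for (i in 1:1000) {
    alpha <- runif(1, 0.01, 0.49)
    R <- sample(ceiling(1 / alpha):300, 1)
    ts <- rnorm(R)
    expect_equal(unname(percentile_ci(ts, alpha)), naive_percentile_ci(ts, alpha))
  }
})

test_that("narrowing the tail probability never narrows the interval", {
  set.seed(23)
  for (i in 1:25) {
    ts <- rnorm(400)
    a1 <- runif(1, 0.01, 0.2)
    a2 <- runif(1, a1, 0.45)
    ci1 <- percentile_ci(ts, a1)  # wider (more central mass)
    ci2 <- percentile_ci(ts, a2)
    expect_lte(ci1[["lower"]], ci2[["lower"]])
    expect_gte(ci1[["upper"]], ci2[["upper"]])
  }
})

test_that("phase assignment requires whole-interval containment in one bin", {
  b <- phase_bins()
  expect_equal(assign_phase(8, 8, b), "G2")
  expect_equal(assign_phase(0, 0, b), "G0")
  expect_equal(assign_phase(6.5, 9.5, b), "G2")
  # spanning the G1/G2 boundary fits in neither bin
  expect_equal(assign_phase(4, 8, b), "unassigned")
  expect_equal(assign_phase(-1, 21, b), "unassigned")
  # G0 wraps circularly: hours just below the period map back by -T
  expect_equal(assign_phase(23, 23.5, b), "G0")
  expect_equal(assign_phase(21, 25, b), "unassigned")
  # shared-boundary point interval: the bin holding theta_hat wins
  expect_equal(assign_phase(6, 6, b, theta_hat = 8), "G2")
  expect_equal(assign_phase(6, 6, b, theta_hat = 4), "G1")
  expect_error(assign_phase(5, 3, b), "exceed")
})

test_that("single-gene analysis recovers a noise-free on-grid cosine", {
  tb <- generate_templates()
  s <- expression_series(2 + cosine_wave(8), default_tp, gene_id = "g8")
  res <- analyze_gene(s, tb, n_replicates = 99, alpha = 0.05, seed = 11,
                      return_replicates = TRUE)
  expect_equal(res$theta_hat, 8)
  expect_equal(res$rho_hat, 1, tolerance = 1e-12)
  expect_true(res$is_circadian)
  expect_equal(res$assigned_bin, "G2")
  expect_lte(res$p_value, 0.05)
  # CI endpoints are order statistics of theta*, hence on the peak-time grid
  rs <- attr(res, "replicate_stats")
  expect_true(all(rs$theta_star %in% tb$peak_times))
  expect_true(res$ci_lower %in% tb$peak_times)
  expect_true(res$ci_upper %in% tb$peak_times)
  # reproducibility: identical seed, identical result
  res2 <- analyze_gene(s, tb, n_replicates = 99, alpha = 0.05, seed = 11)
  expect_identical(res[, names(res2)], res2)
})

test_that("dataset analysis bins high-SNR cosines, skips degenerate rows, is order-invariant", {
  syn <- synthetic_dataset(n_genes = 20, frac_rhythmic = 0.5, noise_sd = 0.15,
                           peak_hours = 8, seed = 21)
  mat <- syn$matrix
  fit <- analyze_dataset(mat, n_replicates = 199, seed = 5)
  res <- fit$results
  rhythmic <- res[res$gene_id %in% syn$truth$gene_id[syn$truth$rhythmic], ]
  expect_true(all(rhythmic$theta_hat == 8))
  expect_gt(mean(rhythmic$assigned_bin == "G2"), 0.8)
  # summary counts sum and percentages recompute from counts
  s <- fit$summary
  body <- s[s$phase != "Total", ]
  expect_equal(sum(body$n_genes), s$n_genes[s$phase == "Total"])
  n_circ <- attr(s, "n_circadian")
  expect_equal(body$pct_of_circadian, round(100 * body$n_genes / n_circ, 2))
  expect_lte(sum(body$n_genes), n_circ)

  # degenerate (constant) row is excluded and logged, totals unaffected
  mat2 <- rbind(mat, flat = rep(3, 12))
  expect_message(fit2 <- analyze_dataset(mat2, n_replicates = 199, seed = 5),
                 "skipped")
  expect_equal(fit2$skipped$gene_id, "flat")
  expect_equal(fit2$summary$n_genes, fit$summary$n_genes)

  # row-order invariance: per-gene seeds derive from identifiers
  perm <- sample(nrow(mat))
  fit3 <- analyze_dataset(mat[perm, ], n_replicates = 199, seed = 5)
  r3 <- fit3$results[order(fit3$results$gene_id), ]
  r1 <- fit$results[order(fit$results$gene_id), ]
  rownames(r1) <- rownames(r3) <- NULL
  expect_equal(r3, r1)
})

test_that("the worked percentage arithmetic recomputes from counts", {
  # 223 assigned of 646 circadian genes is 34.52%
  res <- data.frame(gene_id = sprintf("g%d", 1:646),
                    is_circadian = TRUE,
                    assigned_bin = c(rep("G2", 223), rep("unassigned", 423)),
                    stringsAsFactors = FALSE)
  s <- phase_summary(res)
  expect_equal(s$n_genes[s$phase == "G2"], 223)
  expect_equal(s$pct_of_circadian[s$phase == "G2"], 34.52)
})

test_that("Benjamini-Hochberg gating only tightens the circadian set", {
  syn <- synthetic_dataset(n_genes = 12, frac_rhythmic = 0.5, noise_sd = 0.3,
                           seed = 9)
  raw <- analyze_dataset(syn$matrix, n_replicates = 99, seed = 2)
  bh <- analyze_dataset(syn$matrix, n_replicates = 99, seed = 2, p_adjust = "BH")
  expect_true(all(bh$results$p_adjusted >= bh$results$p_value))
  expect_true(all(bh$results$is_circadian <= raw$results$is_circadian))
})
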