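#' Bootstrap p-value with the add-one convention
#'
#' p = (1 + #\{j : tau*_j > tau_hat\}) / (1 + R), using the strict
#' inequality. The add-one convention guarantees p in \[1/(R+1), 1\] and
#' avoids zero p-values from finite resampling.
#'
#' @param tau_hat Observed test statistic.
#' @param tau_star Numeric vector of R replicate statistics.
#' @return The bootstrap p-value, a number in (0, 1\].
#' @examples
#' bootstrap_pvalue(0.9, c(rep(1, 73), rep(0, 926)))  # 0.074
#' @export
bootstrap_pvalue <- function(tau_hat, tau_star) {
  if (length(tau_star) < 1L) stop("`tau_star` must be nonempty", call. = FALSE)
  if (!is.finite(tau_hat) || !all(is.finite(tau_star))) {
    stop("statistics must be finite", call. = FALSE)
  }
  (1 + sum(tau_star > tau_hat)) / (1 + length(tau_star))
}

#' Bootstrap percentile confidence interval
#'
#' The central 100(1 - 2*alpha)% percentile interval from R bootstrap
#' replicates of an estimator: sort the replicates and take the (R*alpha)-th
#' and (R*(1-alpha))-th order statistics when R*alpha is an integer;
#' otherwise take the k-th and (R + 1 - k)-th with k = floor((R + 1)*alpha).
#' For R = 999 and alpha = 0.025 these are the 25th and 975th ordered
#' elements.
#'
#' @param theta_star Numeric vector of R bootstrap replicates of the
#'   estimator (here: peak times in hours).
#' @param alpha Tail probability per side, in (0, 0.5); R must be large
#'   enough that the lower order-statistic index is at least 1 (i.e.
#'   floor((R + 1) * alpha) >= 1).
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' percentile_ci(1:999, alpha = 0.025)  # 25 975
#' @export
percentile_ci <- function(theta_star, alpha = 0.025) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 0.5) {
    stop("`alpha` must be in (0, 0.5)", call. = FALSE)
  }
  R <- length(theta_star)
  ra <- R * alpha
  if (abs(ra - round(ra)) < 1e-9) {
    lo_i <- as.integer(round(ra))
    hi_i <- as.integer(round(R * (1 - alpha)))
  } else {
    k <- floor((R + 1) * alpha)
    lo_i <- as.integer(k)
    hi_i <- as.integer(R + 1 - k)
  }
  if (lo_i < 1L) {
    stop("too few replicates for the percentile interval at this alpha ",
         "(need floor((R+1)*alpha) >= 1)", call. = FALSE)
  }
  s <- sort(theta_star)
  c(lower = s[lo_i], upper = s[hi_i])
}

# Does bin row `i` of `bins` contain the closed interval [lo, hi]?
# G0 is circular: an interval sitting just below the period wraps to
# negative hours (h -> h - period) before the containment test.
bin_contains <- function(bins, i, lo, hi, period) {
  if (lo >= bins$lower[i] && hi <= bins$upper[i]) return(TRUE)
  if (i == 1L && (lo - period) >= bins$lower[1L] && (hi - period) <= bins$upper[1L]) {
    return(TRUE)
  }
  FALSE
}

#' Assign a confidence interval to a phase bin
#'
#' A gene is confidently assigned to bin Gi exactly when its whole peak-time
#' confidence interval fits inside Gi. The first bin G0 (centred on 0 h) is
#' treated circularly: hours just below the period wrap around by
#' h -> h - T. If a CI endpoint sits exactly on a boundary shared by two
#' bins, the bin containing the point estimate wins; if that is still
#' ambiguous the lower-indexed bin wins.
#'
#' @param ci_lower,ci_upper CI endpoints in hours, `ci_lower <= ci_upper`.
#' @param bins A [phase_bins()] table.
#' @param theta_hat Point estimate of the peak time in hours (tie-breaks).
#' @return A bin label ("G0", "G1", ...) or `"unassigned"`.
#' @examples
#' assign_phase(8, 8, phase_bins())   # "G2"
#' assign_phase(4, 8, phase_bins())   # "unassigned"
#' @export
assign_phase <- function(ci_lower, ci_upper, bins = phase_bins(), theta_hat = ci_lower) {
  stopifnot(inherits(bins, "phase_bins"))
  if (ci_lower > ci_upper) stop("`ci_lower` must not exceed `ci_upper`", call. = FALSE)
  period <- attr(bins, "period")
  hits <- which(vapply(seq_len(nrow(bins)), bin_contains, logical(1L),
                       bins = bins, lo = ci_lower, hi = ci_upper, period = period))
  if (length(hits) == 0L) return("unassigned")
  if (length(hits) > 1L) {
    with_theta <- hits[vapply(hits, bin_contains, logical(1L),
                              bins = bins, lo = theta_hat, hi = theta_hat,
                              period = period)]
    if (length(with_theta) > 0L) hits <- with_theta
  }
  bins$label[hits[1L]]
}

# Per-replicate (rho*, theta*) for an ensemble against a template bank,
# computed in one correlation call: columns of t(replicates) vs template
# columns. Ties at the max go to the smallest phase, as in estimate_phase().
replicate_statistics <- function(ensemble, templates, method = "pearson") {
  cm <- stats::cor(t(ensemble$replicates), templates$values, method = method)
  idx <- max.col(cm, ties.method = "first")
  list(rho_star = cm[cbind(seq_len(nrow(cm)), idx)],
       theta_star = templates$peak_times[idx])
}

#' Full phase-confidence analysis of one gene
#'
#' Runs the whole procedure for one series: estimate the peak time by
#' maximal template correlation; generate R maximum entropy bootstrap
#' replicates and recompute (rho*, theta*) on each with the same template
#' bank; form the bootstrap p-value for the maximum correlation rho_hat and
#' the percentile CI for the peak time; flag the gene circadian when
#' p <= alpha; and assign a phase bin only when the gene is circadian and
#' its whole CI fits inside one bin. The CI is computed and reported
#' regardless of significance.
#'
#' @param series An [expression_series()] or numeric vector.
#' @param templates A [generate_templates()] bank.
#' @param n_replicates Bootstrap replicates R (default 999).
#' @param alpha Significance level for the rhythmicity test (default 0.05).
#' @param ci_alpha Tail probability per side of the percentile CI (default
#'   0.025, i.e. a 95% interval).
#' @param trim Trim proportion for the ME bootstrap tails (default 0.10).
#' @param seed Optional integer seed for the replicate stream.
#' @param method Correlation type passed to the phase estimator.
#' @param return_replicates If `TRUE`, attach the per-replicate statistics
#'   as attribute `"replicate_stats"`.
#' @return A one-row data.frame: `gene_id`, `rho_hat`, `phi_hat`,
#'   `theta_hat`, `p_value`, `ci_lower`, `ci_upper`, `is_circadian`,
#'   `assigned_bin`.
#' @examples
#' tb <- generate_templates()
#' s <- expression_series(2 + cos(2 * pi * seq(0, 44, 4) / 24 - 2 * pi / 3))
#' analyze_gene(s, tb, n_replicates = 99, seed = 1)
#' @export
analyze_gene <- function(series, templates = generate_templates(),
                         n_replicates = 999, alpha = 0.05, ci_alpha = 0.025,
                         trim = 0.10, seed = NULL,
                         method = c("pearson", "spearman"),
                         return_replicates = FALSE) {
  method <- match.arg(method)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  series <- as_series(series, templates)
  est <- estimate_phase(series, templates, method = method)
  ens <- meboot_ensemble(series, n_replicates = n_replicates, trim = trim, seed = seed)
  rs <- replicate_statistics(ens, templates, method = method)
  p <- bootstrap_pvalue(est$rho_hat, rs$rho_star)
  ci <- percentile_ci(rs$theta_star, alpha = ci_alpha)
  circadian <- p <= alpha
  bins <- phase_bins(period = templates$period, k = templates$k)
  bin <- if (circadian) {
    assign_phase(ci[["lower"]], ci[["upper"]], bins, theta_hat = est$theta_hat)
  } else {
    "unassigned"
  }
  out <- data.frame(gene_id = series$gene_id,
                    rho_hat = est$rho_hat, phi_hat = est$phi_hat,
                    theta_hat = est$theta_hat, p_value = p,
                    ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
                    is_circadian = circadian, assigned_bin = bin,
                    stringsAsFactors = FALSE)
  if (return_replicates) attr(out, "replicate_stats") <- rs
  out
}

# Deterministic, platform-independent seed for one gene: a polynomial
# rolling hash of the identifier folded with the master seed, kept below
# 2^31 - 1. Depends only on the identifier, so results are invariant to row
# order and subsetting.
derive_gene_seed <- function(master_seed, gene_id) {
  m <- 2147483647
  h <- as.numeric(master_seed) %% m
  for (code in utf8ToInt(as.character(gene_id))) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

#' Phase-confidence analysis of an expression matrix
#'
#' Applies [analyze_gene()] independently to every row of a genes-by-
#' timepoints matrix. Each gene gets its own reproducible bootstrap stream,
#' derived from the master seed and the gene identifier, so per-gene results
#' do not depend on row order or on which other genes are present.
#' Constant (zero-variance) or otherwise degenerate rows are skipped and
#' reported, not fatal.
#'
#' @param x Numeric matrix or data.frame, genes in rows, timepoints in
#'   columns; rownames are gene identifiers (generated when absent).
#' @param timepoints Sampling times in hours; default 0, 4, ..., 4*(ncol-1).
#' @param period,k Template-bank parameters, see [generate_templates()].
#' @param n_replicates,alpha,ci_alpha,trim,method As in [analyze_gene()].
#' @param seed Master seed (default 1).
#' @param genes Optional character vector restricting the analysis to a
#'   subset of gene identifiers.
#' @param p_adjust `"none"` (default, the per-gene p <= alpha rule) or
#'   `"BH"` for Benjamini-Hochberg adjustment across genes before the
#'   circadian gate.
#' @return An object of class `phase_analysis`: list with `results` (per-gene
#'   data.frame), `summary` (see [phase_summary()]), `skipped` (data.frame of
#'   excluded rows with reasons) and `config` (the exact parameters used).
#' @examples
#' syn <- synthetic_dataset(n_genes = 6, noise_sd = 0.1, seed = 3)
#' fit <- analyze_dataset(syn$matrix, n_replicates = 99, seed = 3)
#' fit$summary
#' @export
analyze_dataset <- function(x, timepoints = NULL, period = 24, k = 3,
                            n_replicates = 999, alpha = 0.05, ci_alpha = 0.025,
                            trim = 0.10, seed = 1, genes = NULL,
                            p_adjust = c("none", "BH"),
                            method = c("pearson", "spearman")) {
  p_adjust <- match.arg(p_adjust)
  method <- match.arg(method)
  x <- as.matrix(x)
  if (nrow(x) < 1L) stop("need at least one gene row", call. = FALSE)
  storage.mode(x) <- "double"
  if (is.null(rownames(x))) rownames(x) <- sprintf("gene_%d", seq_len(nrow(x)))
  rownames(x) <- make.unique(rownames(x), sep = "_")
  if (!is.null(genes)) {
    keep <- rownames(x) %in% genes
    if (!any(keep)) stop("none of the requested genes are present", call. = FALSE)
    x <- x[keep, , drop = FALSE]
  }
  if (is.null(timepoints)) timepoints <- seq(0, by = 4, length.out = ncol(x))
  templates <- generate_templates(timepoints, period = period, k = k)

  rows <- vector("list", nrow(x))
  skipped <- list()
  for (i in seq_len(nrow(x))) {
    gid <- rownames(x)[i]
    gseed <- derive_gene_seed(seed, gid)
    res <- tryCatch(
      analyze_gene(expression_series(x[i, ], timepoints, gene_id = gid),
                   templates, n_replicates = n_replicates, alpha = alpha,
                   ci_alpha = ci_alpha, trim = trim, seed = gseed,
                   method = method),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      skipped[[length(skipped) + 1L]] <- data.frame(gene_id = gid, reason = res,
                                                    stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- res
    }
  }
  results <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(gene_id = character(), reason = character(), stringsAsFactors = FALSE)
  if (nrow(skipped) > 0L) {
    message(nrow(skipped), " gene(s) skipped (degenerate rows)")
  }
  if (is.null(results)) {
    results <- data.frame(gene_id = character(), rho_hat = numeric(),
                          phi_hat = numeric(), theta_hat = numeric(),
                          p_value = numeric(), ci_lower = numeric(),
                          ci_upper = numeric(), is_circadian = logical(),
                          assigned_bin = character(), stringsAsFactors = FALSE)
  }
  bins <- phase_bins(period = period, k = k)
  if (p_adjust == "BH" && nrow(results) > 0L) {
    results$p_adjusted <- stats::p.adjust(results$p_value, method = "BH")
    results$is_circadian <- results$p_adjusted <= alpha
    results$assigned_bin <- ifelse(
      results$is_circadian,
      mapply(assign_phase, results$ci_lower, results$ci_upper,
             theta_hat = results$theta_hat, MoreArgs = list(bins = bins)),
      "unassigned")
  }
  rownames(results) <- NULL
  config <- list(period = period, k = k, n_replicates = n_replicates,
                 alpha = alpha, ci_alpha = ci_alpha, trim = trim, seed = seed,
                 p_adjust = p_adjust, method = method,
                 timepoints = timepoints, rng_kind = RNGkind()[1L])
  structure(list(results = results,
                 summary = phase_summary(results, bins, config),
                 skipped = skipped, config = config),
            class = "phase_analysis")
}

#' Per-bin summary of a phase analysis
#'
#' Counts the circadian genes confidently assigned to each phase bin and
#' expresses each count as a percentage of all circadian genes (so
#' percentages over bins sum to at most 100%; circadian genes whose CI
#' straddles a bin boundary stay unassigned and enter no bin).
#'
#' @param results Per-gene results data.frame from [analyze_dataset()].
#' @param bins A [phase_bins()] table.
#' @param config Optional configuration list stored as an attribute.
#' @return Data.frame with one row per bin plus a `Total` row: columns
#'   `phase`, `lower`, `upper`, `n_genes`, `pct_of_circadian`. Attribute
#'   `n_circadian` holds the circadian total.
#' @export
phase_summary <- function(results, bins = phase_bins(), config = NULL) {
  stopifnot(inherits(bins, "phase_bins"))
  n_circ <- sum(results$is_circadian)
  counts <- vapply(bins$label, function(lb) {
    sum(results$is_circadian & results$assigned_bin == lb)
  }, integer(1L))
  pct <- if (n_circ > 0) round(100 * counts / n_circ, 2) else rep(0, length(counts))
  out <- data.frame(phase = c(bins$label, "Total"),
                    lower = c(bins$lower, NA), upper = c(bins$upper, NA),
                    n_genes = c(counts, sum(counts)),
                    pct_of_circadian = c(pct, round(sum(pct), 2)),
                    stringsAsFactors = FALSE)
  attr(out, "n_circadian") <- n_circ
  attr(out, "config") <- config
  out
}

#' @export
print.phase_analysis <- function(x, ...) {
  cat("Phase-confidence analysis: ", nrow(x$results), " genes (",
      sum(x$results$is_circadian), " circadian, ",
      sum(x$results$assigned_bin != "unassigned"), " confidently binned), R = ",
      x$config$n_replicates, ", alpha = ", x$config$alpha, "\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Barplot of per-bin gene counts
#'
#' @param summary A summary table from [phase_summary()] (or a
#'   `phase_analysis` object).
#' @param ... Passed to [graphics::barplot()].
#' @export
plot_phase_counts <- function(summary, ...) {
  if (inherits(summary, "phase_analysis")) summary <- summary$summary
  s <- summary[summary$phase != "Total", ]
  graphics::barplot(s$n_genes, names.arg = s$phase,
                    xlab = "Phase bin", ylab = "Number of genes", ...)
  invisible(NULL)
}
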