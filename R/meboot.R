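#' Maximum entropy bootstrap: intermediate quantities
#'
#' Prepares everything the maximum entropy (ME) bootstrap needs for one
#' series: the order statistics x_(1) <= ... <= x_(n) with the ordering
#' index, the intermediate points z_t = (x_(t) + x_(t+1))/2, the tail limits
#' z_0 = x_(1) - m_trm and z_n = x_(n) + m_trm where m_trm is the trimmed
#' mean of the successive order-statistic spacings, and the desired
#' per-interval means m_1, ..., m_n of the mean-preserving ME density:
#' m_1 = 0.75 x_(1) + 0.25 x_(2),
#' m_t = 0.25 x_(t-1) + 0.5 x_(t) + 0.25 x_(t+1) for interior t,
#' m_n = 0.25 x_(n-1) + 0.75 x_(n).
#'
#' Sorting is stable, so tied values keep their original relative order and
#' the ordering index is deterministic.
#'
#' @param series An [expression_series()] or numeric vector, length >= 2,
#'   finite.
#' @param trim Trim proportion in \[0, 0.5) for the trimmed mean of spacings
#'   (default 0.10, the established ME-bootstrap convention).
#' @return An object of class `meboot_intermediate`: list with `n`,
#'   `order_index` (positions of the sorted values in the original series),
#'   `sorted_values`, `midpoints`, `z_lower`, `z_upper`, `grid` (the n+1
#'   support knots z_0, z_1, ..., z_n) and `desired_means`.
#' @examples
#' mi <- meboot_intermediate(c(4, 12, 36, 20, 8), trim = 0)
#' mi$midpoints  # 6 10 16 28
#' @export
meboot_intermediate <- function(series, trim = 0.10) {
  x <- if (inherits(series, "expression_series")) series$values else as.numeric(series)
  n <- length(x)
  if (n < 2L) stop("series too short for resampling (need n >= 2)", call. = FALSE)
  if (!all(is.finite(x))) stop("series contains non-finite values", call. = FALSE)
  if (!is.finite(trim) || trim < 0 || trim >= 0.5) {
    stop("`trim` must be in [0, 0.5)", call. = FALSE)
  }
  ord <- order(x)                     # stable: ties keep original order
  xs <- x[ord]
  mids <- (xs[-n] + xs[-1L]) / 2
  m_trm <- mean(diff(xs), trim = trim)
  z_lower <- xs[1L] - m_trm
  z_upper <- xs[n] + m_trm
  dm <- numeric(n)
  dm[1L] <- 0.75 * xs[1L] + 0.25 * xs[2L]
  if (n > 2L) {
    t_int <- 2:(n - 1L)
    dm[t_int] <- 0.25 * xs[t_int - 1L] + 0.5 * xs[t_int] + 0.25 * xs[t_int + 1L]
  }
  dm[n] <- 0.25 * xs[n - 1L] + 0.75 * xs[n]
  structure(list(n = n, order_index = ord, sorted_values = xs,
                 midpoints = mids, z_lower = z_lower, z_upper = z_upper,
                 grid = c(z_lower, mids, z_upper),
                 desired_means = dm, trim = trim, m_trm = m_trm),
            class = "meboot_intermediate")
}

#' @export
print.meboot_intermediate <- function(x, ...) {
  cat("ME bootstrap intermediate: n = ", x$n, ", support [",
      format(x$z_lower), ", ", format(x$z_upper), "], m_trm = ",
      format(x$m_trm), "\n", sep = "")
  invisible(x)
}

#' Dump ME bootstrap intermediates as plain text
#'
#' Writes the sorted values, support knots and desired interval means to a
#' text connection for inspection.
#'
#' @param intermediate A [meboot_intermediate()] object.
#' @param file Passed to [utils::write.table()]; default prints to stdout.
#' @export
dump_meboot_intermediate <- function(intermediate, file = "") {
  stopifnot(inherits(intermediate, "meboot_intermediate"))
  df <- data.frame(interval = seq_len(intermediate$n),
                   z_left = intermediate$grid[-(intermediate$n + 1L)],
                   z_right = intermediate$grid[-1L],
                   desired_mean = intermediate$desired_means)
  utils::write.table(df, file = file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Quantile function of the maximum entropy density
#'
#' The ME density places probability mass 1/n on each interval between
#' consecutive support knots z_0 < z_1 < ... < z_n and is uniform within each
#' interval, so the quantile function is the piecewise-linear interpolant
#' through the points (t/n, z_t). Interior intervals then carry exactly the
#' desired means m_2, ..., m_(n-1); the two tail intervals miss theirs by
#' -m_trm/2 and +m_trm/2, which cancel, so the density's overall mean equals
#' the mean of the desired interval means exactly (the mean-preserving
#' constraint).
#'
#' @param intermediate A [meboot_intermediate()] object.
#' @param u Numeric vector of probabilities in \[0, 1\].
#' @return Quantiles Q(u), same length as `u`; monotone non-decreasing in
#'   `u`, with Q(0) = z_0, Q(t/n) = z_t and Q(1) = z_n.
#' @export
me_quantile <- function(intermediate, u) {
  stopifnot(inherits(intermediate, "meboot_intermediate"))
  u <- as.numeric(u)
  if (any(!is.finite(u)) || any(u < 0) || any(u > 1)) {
    stop("`u` must lie in [0, 1]", call. = FALSE)
  }
  n <- intermediate$n
  stats::approx(x = (0:n) / n, y = intermediate$grid, xout = u,
                method = "linear", ties = "ordered")$y
}

#' One maximum entropy bootstrap replicate
#'
#' Evaluates the ME quantile function at n uniform draws, sorts the
#' quantiles, and places them back in the original series' rank positions
#' via the ordering index. The replicate therefore has exactly the original
#' rank pattern (this is what carries the dependence structure of the series
#' into the replicate) and lies within \[z_0, z_n\].
#'
#' @param intermediate A [meboot_intermediate()] object (or an
#'   [expression_series()] / numeric vector, in which case `trim` is used to
#'   build the intermediate).
#' @param draws Numeric vector of n uniform(0,1) draws. If `NULL`, drawn from
#'   the current RNG stream.
#' @param trim Trim proportion, used only when `intermediate` is raw data.
#' @return Numeric replicate series of length n.
#' @export
meboot_replicate <- function(intermediate, draws = NULL, trim = 0.10) {
  if (!inherits(intermediate, "meboot_intermediate")) {
    intermediate <- meboot_intermediate(intermediate, trim = trim)
  }
  n <- intermediate$n
  if (is.null(draws)) draws <- stats::runif(n)
  if (length(draws) != n) stop("`draws` must have length n", call. = FALSE)
  q <- sort(me_quantile(intermediate, draws))
  out <- numeric(n)
  out[intermediate$order_index] <- q
  out
}

#' Maximum entropy bootstrap ensemble
#'
#' Generates R replicate series from one seeded uniform stream. Draws are
#' consumed in R blocks of n (replicate-major order), so the ensemble is
#' reproducible given the seed and the session RNG kind (recorded in the
#' result).
#'
#' @param series An [expression_series()] or numeric vector.
#' @param n_replicates Number of replicates R (default 999).
#' @param trim Trim proportion for the tail limits (default 0.10).
#' @param seed Optional integer seed. When supplied, the RNG state is set
#'   locally and restored on exit.
#' @return An object of class `meboot_ensemble`: list with `replicates`
#'   (R x n matrix, one replicate per row), `intermediate`, `n_replicates`,
#'   `seed` and `rng_kind`.
#' @examples
#' ens <- meboot_ensemble(c(4, 12, 36, 20, 8), n_replicates = 99, seed = 1)
#' dim(ens$replicates)
#' @export
meboot_ensemble <- function(series, n_replicates = 999, trim = 0.10, seed = NULL) {
  if (length(n_replicates) != 1L || !is.finite(n_replicates) ||
      n_replicates < 1 || n_replicates != round(n_replicates)) {
    stop("`n_replicates` must be a positive integer", call. = FALSE)
  }
  R <- as.integer(n_replicates)
  intermediate <- meboot_intermediate(series, trim = trim)
  n <- intermediate$n
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
  }
  # replicate-major draws: row b of `um` is the b-th block of n uniforms
  um <- matrix(stats::runif(R * n), nrow = R, ncol = n, byrow = TRUE)
  qm <- matrix(me_quantile(intermediate, as.vector(t(um))),
               nrow = R, ncol = n, byrow = TRUE)
  qs <- matrix(qm[order(row(qm), qm)], nrow = R, ncol = n, byrow = TRUE)  # row-wise sort
  inv <- integer(n)
  inv[intermediate$order_index] <- seq_len(n)
  reps <- qs[, inv, drop = FALSE]
  structure(list(replicates = reps, intermediate = intermediate,
                 n_replicates = R, seed = seed, rng_kind = RNGkind()[1L]),
            class = "meboot_ensemble")
}

#' @export
print.meboot_ensemble <- function(x, ...) {
  cat("ME bootstrap ensemble: ", x$n_replicates, " replicates of length ",
      x$intermediate$n, "\n", sep = "")
  invisible(x)
}
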