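#' Expression time series for one gene
#'
#' Bundles one gene's ordered measurements with their sampling times. The
#' default time axis is the common circadian design of 12 samples at 4-h
#' spacing over two cycles (t = 0, 4, ..., 44 h).
#'
#' @param values Numeric vector of expression measurements, length >= 4, all
#'   finite.
#' @param timepoints Numeric vector of sampling times in hours, strictly
#'   increasing, same length as `values`.
#' @param gene_id Character label for the gene.
#' @return An object of class `expression_series`: a list with elements
#'   `gene_id`, `values` and `timepoints`.
#' @examples
#' s <- expression_series(5 + cos(2 * pi * seq(0, 44, 4) / 24))
#' @export
expression_series <- function(values,
                              timepoints = seq(0, by = 4, length.out = length(values)),
                              gene_id = "gene") {
  values <- as.numeric(values)
  timepoints <- as.numeric(timepoints)
  if (length(values) != length(timepoints)) {
    stop("`values` and `timepoints` must have the same length", call. = FALSE)
  }
  if (length(values) < 4L) {
    stop("an expression series needs at least 4 timepoints", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("`values` must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  if (any(diff(timepoints) <= 0)) {
    stop("`timepoints` must be strictly increasing", call. = FALSE)
  }
  structure(list(gene_id = as.character(gene_id)[1L],
                 values = values, timepoints = timepoints),
            class = "expression_series")
}

# Coerce numeric input to an expression_series on the template's time axis.
as_series <- function(x, templates = NULL) {
  if (inherits(x, "expression_series")) return(x)
  tp <- if (is.null(templates)) seq(0, by = 4, length.out = length(x)) else templates$timepoints
  expression_series(x, timepoints = tp)
}

#' @export
print.expression_series <- function(x, ...) {
  cat("Expression series '", x$gene_id, "': ", length(x$values),
      " points, t = ", x$timepoints[1L], "..", x$timepoints[length(x$timepoints)],
      " h\n", sep = "")
  invisible(x)
}

#' Generate the cosine template bank
#'
#' Builds 2k ideal cosine waves C_phi(t) = cos(2*pi*t/T - phi) with phases
#' phi = i*pi/k (i = 0, ..., 2k-1), evaluated at the sampling times. With the
#' defaults (T = 24 h, k = 3) the six template peaks fall exactly on the
#' sampling grid at 0, 4, 8, 12, 16 and 20 h, so the resolution of the
#' estimated peak time matches the resolution of the experiment.
#'
#' @param timepoints Sampling times in hours.
#' @param period Oscillation period T in hours (default 24).
#' @param k Resolution parameter: the bank holds 2k templates with peaks
#'   T/(2k) hours apart (default 3, i.e. six templates 4 h apart).
#' @return An object of class `template_set`: list with `period`, `k`,
#'   `timepoints`, `phases` (radians), `peak_times` (hours) and `values`
#'   (length(timepoints) x 2k matrix, one column per template).
#' @examples
#' tb <- generate_templates(seq(0, 44, 4))
#' tb$peak_times  # 0 4 8 12 16 20
#' @export
generate_templates <- function(timepoints = seq(0, 44, by = 4), period = 24, k = 3) {
  timepoints <- as.numeric(timepoints)
  if (length(timepoints) == 0L) stop("`timepoints` must be nonempty", call. = FALSE)
  if (!is.finite(period) || period <= 0) stop("`period` must be positive", call. = FALSE)
  if (length(k) != 1L || !is.finite(k) || k < 1 || k != round(k)) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  k <- as.integer(k)
  phases <- (seq_len(2L * k) - 1L) * pi / k
  values <- vapply(phases,
                   function(phi) cos(2 * pi * timepoints / period - phi),
                   numeric(length(timepoints)))
  peak_times <- phases * period / (2 * pi)
  colnames(values) <- sprintf("phi_%d_pi_%d", round(phases / pi * k), k)
  structure(list(period = period, k = k, timepoints = timepoints,
                 phases = phases, peak_times = peak_times, values = values),
            class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat("Template bank: ", 2L * x$k, " cosines, period ", x$period,
      " h, peak times ", paste(round(x$peak_times, 3), collapse = ", "),
      " h\n", sep = "")
  invisible(x)
}

#' Correlation of a series with every template
#'
#' @param series An [expression_series()] or a numeric vector (assumed to lie
#'   on the template time axis).
#' @param templates A [generate_templates()] bank on the same time axis.
#' @param method Correlation type, `"pearson"` (default) or `"spearman"`.
#' @return Numeric vector of length 2k, element i the correlation with the
#'   template of phase (i-1)*pi/k.
#' @export
correlation_vector <- function(series, templates, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  series <- as_series(series, templates)
  if (length(series$values) != nrow(templates$values)) {
    stop("series length does not match the template evaluation grid", call. = FALSE)
  }
  if (stats::sd(series$values) == 0) {
    stop("degenerate series: constant values, correlation undefined", call. = FALSE)
  }
  as.vector(stats::cor(series$values, templates$values, method = method))
}

#' Estimate a gene's peak time by maximal template correlation
#'
#' The estimate is the peak time of the best-correlated template:
#' rho_hat = max_i cor(x, C_i), phi_hat the phase of the arg-max template and
#' theta_hat = phi_hat * T / (2*pi) hours. Ties in the maximum are broken
#' towards the smallest phase.
#'
#' @inheritParams correlation_vector
#' @return An object of class `phase_estimate`: list with `rho_hat`,
#'   `phi_hat` (radians), `theta_hat` (hours) and the full correlation
#'   vector `correlations`.
#' @examples
#' tb <- generate_templates()
#' s <- expression_series(5 + 3 * cos(2 * pi * seq(0, 44, 4) / 24 - pi / 3))
#' estimate_phase(s, tb)$theta_hat  # 4
#' @export
estimate_phase <- function(series, templates, method = c("pearson", "spearman")) {
  rho <- correlation_vector(series, templates, method = method)
  i <- which.max(rho)  # first maximum = smallest phase on ties
  structure(list(rho_hat = rho[i],
                 phi_hat = templates$phases[i],
                 theta_hat = templates$peak_times[i],
                 correlations = rho),
            class = "phase_estimate")
}

#' @export
print.phase_estimate <- function(x, ...) {
  cat(sprintf("Phase estimate: theta_hat = %g h (phi_hat = %g rad, rho_hat = %.4f)\n",
              x$theta_hat, x$phi_hat, x$rho_hat))
  invisible(x)
}

#' Phase bins tiling the period
#'
#' Bin Gi is the T/(2k)-hour interval centred on template peak time i*T/(2k).
#' At the defaults this reproduces the six 4-h bins
#' G0 = \[-2, 2\], G1 = \[2, 6\], ..., G5 = \[18, 22\]. G0 straddles zero; for
#' containment tests it is treated circularly (hours near T wrap to negative
#' hours), see [assign_phase()].
#'
#' @param period Period T in hours.
#' @param k Resolution parameter; 2k bins of width T/(2k).
#' @return A data.frame of class `phase_bins` with columns `label`, `lower`,
#'   `upper` (hours) and attributes `period` and `k`.
#' @export
phase_bins <- function(period = 24, k = 3) {
  if (!is.finite(period) || period <= 0) stop("`period` must be positive", call. = FALSE)
  if (length(k) != 1L || !is.finite(k) || k < 1 || k != round(k)) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  k <- as.integer(k)
  w <- period / (2 * k)
  centers <- (seq_len(2L * k) - 1L) * w
  out <- data.frame(label = sprintf("G%d", seq_len(2L * k) - 1L),
                    lower = centers - w / 2, upper = centers + w / 2,
                    stringsAsFactors = FALSE)
  attr(out, "period") <- period
  attr(out, "k") <- k
  class(out) <- c("phase_bins", "data.frame")
  out
}
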