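#' Synthetic expression matrix with known rhythmic ground truth
#'
#' Generates a genes-by-timepoints matrix mimicking the layout of a bulk
#' circadian time course: rhythmic genes are noisy cosines
#' baseline + amplitude * cos(2*pi*t/period - phi) and non-rhythmic genes are
#' baseline plus noise. The companion truth table records, per gene, the true
#' phase, peak hour and rhythmic flag, so every stage of the pipeline can be
#' checked against known answers.
#'
#' @param n_genes Number of genes (rows).
#' @param frac_rhythmic Fraction of genes that oscillate, in \[0, 1\]
#'   (default 0.5).
#' @param amplitude Cosine amplitude: a single value, or a length-2 range
#'   sampled uniformly per gene (default 1).
#' @param baseline Mean expression level (default 5, a typical log2 intensity).
#' @param noise_sd Standard deviation of the additive noise (default 0.2,
#'   i.e. a high signal-to-noise series at the default amplitude).
#' @param peak_hours True peak times for rhythmic genes: `NULL` (default)
#'   samples uniformly from the on-grid template peaks \{0, 4, ..., 20\}; a
#'   numeric vector is recycled across rhythmic genes (off-grid values such
#'   as 6 probe the between-timepoints ambiguity).
#' @param timepoints Sampling times in hours (default 0, 4, ..., 44).
#' @param period Oscillation period in hours (default 24).
#' @param noise `"gaussian"` (default) or `"lognormal"` for multiplicative
#'   positive noise of matching log-sd.
#' @param seed Integer seed; the generator is fully reproducible.
#' @return A list with `matrix` (numeric, rownames gene_1, ...) and `truth`
#'   (data.frame: `gene_id`, `rhythmic`, `phase_phi` in radians, `peak_hour`,
#'   `amplitude`).
#' @examples
#' syn <- synthetic_dataset(n_genes = 10, noise_sd = 0, peak_hours = 8, seed = 1)
#' syn$truth$peak_hour
#' @export
synthetic_dataset <- function(n_genes = 100, frac_rhythmic = 0.5, amplitude = 1,
                              baseline = 5, noise_sd = 0.2, peak_hours = NULL,
                              timepoints = seq(0, 44, by = 4), period = 24,
                              noise = c("gaussian", "lognormal"), seed = 1) {
  noise <- match.arg(noise)
  if (frac_rhythmic < 0 || frac_rhythmic > 1) {
    stop("`frac_rhythmic` must be in [0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (!length(amplitude) %in% c(1L, 2L)) {
    stop("`amplitude` must be one value or a range of two", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  n_rhythmic <- round(n_genes * frac_rhythmic)
  rhythmic <- rep(c(TRUE, FALSE), c(n_rhythmic, n_genes - n_rhythmic))
  grid_peaks <- seq(0, period - period / 6, by = period / 6)
  peaks <- numeric(n_genes)
  if (n_rhythmic > 0) {
    peaks[rhythmic] <- if (is.null(peak_hours)) {
      sample(grid_peaks, n_rhythmic, replace = TRUE)
    } else {
      rep_len(as.numeric(peak_hours), n_rhythmic)
    }
  }
  amps <- if (length(amplitude) == 2L) {
    stats::runif(n_genes, amplitude[1L], amplitude[2L])
  } else {
    rep(amplitude, n_genes)
  }
  amps[!rhythmic] <- 0
  phi <- 2 * pi * peaks / period

  signal <- t(vapply(seq_len(n_genes), function(i) {
    if (rhythmic[i]) {
      baseline + amps[i] * cos(2 * pi * timepoints / period - phi[i])
    } else {
      rep(baseline, length(timepoints))
    }
  }, numeric(length(timepoints))))
  eps <- matrix(stats::rnorm(n_genes * length(timepoints), 0, noise_sd),
                nrow = n_genes)
  mat <- if (noise == "gaussian") signal + eps else signal * exp(eps)
  rownames(mat) <- sprintf("gene_%d", seq_len(n_genes))
  colnames(mat) <- sprintf("t%d", timepoints)

  truth <- data.frame(gene_id = rownames(mat), rhythmic = rhythmic,
                      phase_phi = ifelse(rhythmic, phi, NA_real_),
                      peak_hour = ifelse(rhythmic, peaks, NA_real_),
                      amplitude = amps, stringsAsFactors = FALSE)
  list(matrix = mat, truth = truth)
}
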