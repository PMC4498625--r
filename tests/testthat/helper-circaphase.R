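# Shared test utilities

default_tp <- seq(0, 44, by = 4)

# textbook Pearson correlation, independent of stats::cor
pearson_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

cosine_wave <- function(peak_hour, timepoints = default_tp, period = 24,
                        amplitude = 1, baseline = 0) {
  baseline + amplitude * cos(2 * pi * timepoints / period -
                               2 * pi * peak_hour / period)
}

# brute-force percentile interval: sort and index by the stated rule
naive_percentile_ci <- function(theta_star, alpha) {
  R <- length(theta_star)
  s <- sort(theta_star)
  ra <- R * alpha
  if (abs(ra - round(ra)) < 1e-9) {
    c(s[round(ra)], s[round(R * (1 - alpha))])
  } else {
    k <- floor((R + 1) * alpha)
    c(s[k], s[R + 1 - k])
  }
}
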