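Package: circaphase
Title: Confidence in Peak-Time Assignment for Rhythmic Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies confidence in the phase (peak time) of rhythmically
    expressed genes measured in short time series. Peak time is estimated by
    maximal Pearson correlation against a bank of ideal cosine templates whose
    peaks sit on the sampling grid. Uncertainty is assessed with the maximum
    entropy bootstrap for dependent series: replicate series yield a bootstrap
    p-value for rhythmicity and a percentile confidence interval for the peak
    time, and a gene is confidently assigned to a discrete phase bin only when
    its whole confidence interval fits inside one bin. Includes readers and
    writers for plain-text expression matrices, a synthetic data generator
    with known ground truth, and a command-line driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, optparse
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
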