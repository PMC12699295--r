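#' Percentile bootstrap confidence interval
#'
#' @param x numeric vector of observations.
#' @param stat function mapping a vector to a scalar statistic.
#' @param n_boot number of resamples.
#' @param conf confidence level.
#' @return length-2 numeric vector (lower, upper).
#' @export
boot_ci <- function(x, stat = mean, n_boot = 1000L, conf = 0.95) {
  n <- length(x)
  reps <- vapply(seq_len(n_boot),
                 function(i) stat(x[sample.int(n, n, replace = TRUE)]),
                 numeric(1))
  a <- (1 - conf) / 2
  unname(stats::quantile(reps, c(a, 1 - a), na.rm = TRUE))
}

# run-length dwell segments of an integer state path
path_dwells <- function(path, sample_rate_hz) {
  r <- rle(as.integer(path))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(
    state = r$values,
    start_idx = starts,
    n_samples = r$lengths,
    start_s = (starts - 1L) / sample_rate_hz,
    duration_s = r$lengths / sample_rate_hz
  )
}
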