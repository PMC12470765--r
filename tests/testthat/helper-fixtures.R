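# Shared fixtures built in code.

# A noise-free piecewise-linear ratio trace holding one triangular peak:
# baseline 1.0, apex 1.5 at t = 10 s, linear rise from t = 8 s, linear
# return to baseline at t = 14 s, sampled at 2 Hz on [0, 20] s.
triangle_trace <- function(dt = 0.5) {
  t <- seq(0, 20, by = dt)
  r <- rep(1, length(t))
  up <- t >= 8 & t <= 10
  dn <- t > 10 & t <= 14
  r[up] <- 1 + 0.5 * (t[up] - 8) / 2
  r[dn] <- 1.5 - 0.5 * (t[dn] - 10) / 4
  tibble::tibble(time_s = t, ratio = r, baseline = 1)
}

# Independent brute-force sliding percentile (the oracle for
# estimate_baseline): for each sample, the percentile of the raw ratio in
# a centered window, clipped at the record edges.
brute_sliding_percentile <- function(x, width, prob) {
  n <- length(x)
  half <- width %/% 2
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    unname(quantile(x[lo:hi], prob, names = FALSE))
  }, numeric(1))
}

# Match detected apexes to ground-truth apexes within a tolerance (s);
# returns indices into `det` (NA for misses), greedily by distance.
match_peaks <- function(det_t, truth_t, tol = 3) {
  vapply(truth_t, function(ta) {
    if (!length(det_t)) return(NA_integer_)
    d <- abs(det_t - ta)
    if (min(d) < tol) which.min(d) else NA_integer_
  }, integer(1))
}
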