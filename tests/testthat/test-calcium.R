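test_that("ratio computation is pointwise and bleach-cancelling", {
  rec <- tibble::tibble(time_s = 0:9, f480 = 1, f535 = 2)
  expect_equal(compute_ratio(rec)$ratio, rep(2, 10))
  rec$f535 <- rec$f480
  expect_equal(compute_ratio(rec)$ratio, rep(1, 10))
  rec2 <- tibble::tibble(time_s = 0:9, f480 = 3 * exp(-0.001 * (0:9)),
                         f535 = 5 * exp(-0.001 * (0:9)))
  expect_equal(compute_ratio(rec2)$ratio, rep(5 / 3, 10), tolerance = 1e-14)
  expect_error(compute_ratio(tibble::tibble(time_s = 0:2, f480 = c(1, 0, 1),
                                            f535 = 1)), "f480")
})

test_that("baseline tracks the resting ratio through transients and drift", {
  cfg <- analysis_config()
  t <- seq(0, 900, by = 0.4)
  flat <- tibble::tibble(time_s = t, ratio = 1, baseline = NA_real_)
  expect_equal(estimate_baseline(flat, cfg)$baseline, rep(1, length(t)))
  # one 4-s triangular transient in a 900-s noise-free record
  r <- rep(1, length(t))
  tri <- abs(t - 450) <= 2
  r[tri] <- 1 + 0.5 * (1 - abs(t[tri] - 450) / 2)
  one <- tibble::tibble(time_s = t, ratio = r, baseline = NA_real_)
  expect_lt(max(abs(estimate_baseline(one, cfg)$baseline - 1)), 1e-6)
  # linear drift, no transients: baseline within one window of the line
  dr <- tibble::tibble(time_s = t, ratio = 1 + 0.1 * t / 900,
                       baseline = NA_real_)
  b <- estimate_baseline(dr, cfg)$baseline
  lag_tol <- 0.1 * cfg$baseline_window_s / 900  # drift over one window
  expect_lt(max(abs(b - dr$ratio)), lag_tol + 1e-9)
  expect_error(estimate_baseline(flat[1:50, ], cfg), "window")
})

test_that("baseline equals the brute-force sliding percentile when smoothed alike", {
  cfg <- analysis_config(baseline_window_s = 20, baseline_prob = 0.1)
  set.seed(3)
  t <- seq(0, 200, by = 0.4)
  tr <- tibble::tibble(time_s = t, ratio = 1 + 0.05 * sin(t / 30),
                       baseline = NA_real_)
  got <- estimate_baseline(tr, cfg, sigma = 0)$baseline
  w <- round(20 / 0.4); if (w %% 2 == 0) w <- w + 1
  brute <- brute_sliding_percentile(tr$ratio, w, 0.1)
  brute <- vapply(seq_along(brute), function(i) {
    lo <- max(1, i - w %/% 2); hi <- min(length(brute), i + w %/% 2)
    mean(brute[lo:hi])
  }, numeric(1))
  expect_equal(got, brute, tolerance = 1e-12)
})

test_that("candidate detection finds isolated transients at the right times", {
  cfg <- analysis_config()
  t <- seq(0, 900, by = 0.4)
  flat <- estimate_baseline(tibble::tibble(time_s = t, ratio = 1,
                                           baseline = NA_real_), cfg)
  expect_equal(nrow(detect_peaks(flat, cfg)), 0)
  sim <- simulate_fret_recording(transient_spec(t0 = 300, A = 0.1),
                                 duration = 900, noise_sd = 0.004, seed = 2)
  fit <- analyze_recording(sim$recording, cfg)
  expect_equal(nrow(fit$candidates), 1)
  expect_lt(abs(fit$candidates$t_apex - sim$truth$t_apex), 0.4 + 1e-9)
  two <- simulate_fret_recording(transient_spec(t0 = c(300, 360), A = 0.1),
                                 duration = 900, noise_sd = 0.004, seed = 2)
  cand <- analyze_recording(two$recording, cfg)$candidates
  expect_equal(nrow(cand), 2)
  expect_true(all(diff(cand$t_apex) > 0))
})

test_that("mirror score separates anti-phase signals from co-varying ones", {
  t <- seq(0, 10, by = 0.1)
  rec <- tibble::tibble(time_s = t, f535 = 1 + 0.1 * sin(t),
                        f480 = 1 - 0.1 * sin(t))
  ms <- mirror_change_score(rec, 1L, which.max(rec$f535), nrow(rec))
  expect_equal(ms$score, -1, tolerance = 1e-10)
  rec2 <- tibble::tibble(time_s = t, f535 = 1 + 0.1 * sin(t),
                         f480 = 1 + 0.1 * sin(t))
  ms2 <- mirror_change_score(rec2, 1L, which.max(rec2$f535), nrow(rec2))
  expect_equal(ms2$score, 1, tolerance = 1e-10)
  expect_false(ms2$sign_ok)
  rec3 <- tibble::tibble(time_s = t, f535 = 1 + 0.1 * sin(t), f480 = 1)
  expect_error(mirror_change_score(rec3, 1L, 5L, length(t)), "constant")
})

test_that("triangular peak metrics match the closed form", {
  tr <- triangle_trace()
  i_start <- which(tr$time_s == 8)
  i_apex <- which(tr$time_s == 10)
  i_end <- which(tr$time_s == 14)
  pk <- measure_peak(tr, i_start, i_apex, i_end)
  expect_equal(pk$height_pct, 50)
  expect_equal(pk$rise_time_s, 2)
  expect_equal(pk$decay_time_s, 4)
  expect_equal(pk$rise_rate_pct_per_s, 25)
  expect_equal(pk$decay_rate_pct_per_s, 12.5)
  expect_equal(pk$half_height_width_s, 3)  # crossings of 1.25 at t = 9, 12
  expect_equal(pk$total_width_s, 6)
})

test_that("a symmetric triangle has equal rise and decay kinetics", {
  t <- seq(0, 20, by = 0.5)
  r <- rep(1, length(t))
  seg <- abs(t - 10) <= 3
  r[seg] <- 1 + 0.4 * (1 - abs(t[seg] - 10) / 3)
  tr <- tibble::tibble(time_s = t, ratio = r, baseline = 1)
  pk <- measure_peak(tr, which(t == 7), which(t == 10), which(t == 13))
  expect_equal(pk$rise_time_s, pk$decay_time_s)
  expect_equal(pk$rise_rate_pct_per_s, pk$decay_rate_pct_per_s)
})

test_that("degenerate intervals are rejected", {
  tr <- triangle_trace()
  expect_error(measure_peak(tr, 1L, 2L, 3L), "height")
  expect_error(measure_peak(tr, 1L, 2L, 2L), "3 samples")
})

test_that("full analysis recovers simulated transients against the oracle", {
  tr <- transient_spec(t0 = seq(80, 680, by = 120), A = 0.1)
  sim <- simulate_fret_recording(tr, duration = 900, noise_sd = 0.01,
                                 seed = 21)
  fit <- analyze_recording(sim$recording)
  expect_equal(nrow(fit$peaks), 6)
  m <- match_peaks(fit$peaks$t_apex, sim$truth$t_apex)
  expect_true(all(!is.na(m)))
  err <- abs(fit$peaks$half_height_width_s[m] - sim$truth$half_height_width_s)
  expect_true(all(err <= 0.4))
})

test_that("recordings with only same-sign artifacts yield zero accepted peaks", {
  art <- transient_spec(t0 = c(150, 450, 700), A = c(0.1, 0.3, 0.6))
  sim <- simulate_fret_recording(NULL, artifacts = art, duration = 900,
                                 seed = 31)
  fit <- analyze_recording(sim$recording)
  expect_equal(nrow(fit$peaks), 0)
  expect_equal(fit$summary$n_peaks, 0)
})

test_that("an event-free recording reports n_peaks = 0", {
  sim <- simulate_fret_recording(NULL, duration = 900, seed = 32)
  fit <- analyze_recording(sim$recording)
  expect_equal(nrow(fit$peaks), 0)
  expect_true(is.na(fit$summary$mean_height_pct))
})

test_that("rates and times reproduce the height by construction", {
  sim <- simulate_fret_recording(transient_spec(t0 = c(100, 300, 500),
                                                A = 0.12),
                                 duration = 900, seed = 33)
  pk <- analyze_recording(sim$recording)$peaks
  expect_gt(nrow(pk), 0)
  expect_equal(pk$rise_rate_pct_per_s * pk$rise_time_s, pk$height_pct,
               tolerance = 1e-12)
  expect_equal(pk$decay_rate_pct_per_s * pk$decay_time_s, pk$height_pct,
               tolerance = 1e-12)
  expect_true(all(pk$half_height_width_s <= pk$total_width_s))
  expect_true(all(pk$t_start < pk$t_apex & pk$t_apex < pk$t_end))
})

test_that("analysis is deterministic and bleach-invariant", {
  tr <- transient_spec(t0 = c(150, 400, 650), A = 0.1)
  sim <- simulate_fret_recording(tr, duration = 900, noise_sd = 0, seed = 1)
  f1 <- analyze_recording(sim$recording)
  f2 <- analyze_recording(sim$recording)
  expect_identical(f1$peaks, f2$peaks)
  bl <- sim$recording
  g <- exp(-0.0015 * bl$time_s)
  bl$f480 <- bl$f480 * g; bl$f535 <- bl$f535 * g
  f3 <- analyze_recording(bl)
  expect_equal(nrow(f3$peaks), nrow(f1$peaks))
  for (col in c("height_pct", "half_height_width_s", "rise_time_s",
                "decay_time_s", "rise_rate_pct_per_s",
                "decay_rate_pct_per_s")) {
    expect_equal(f3$peaks[[col]], f1$peaks[[col]], tolerance = 1e-9)
  }
})

test_that("group summaries pool or average per recording as requested", {
  pk <- tibble::tibble(group = factor(c("a", "a", "b"),
                                      levels = c("a", "b", "c")),
                       recording_id = c("r1", "r1", "r2"),
                       height_pct = c(10, 30, 20),
                       half_height_width_s = c(1, 3, 2))
  pooled <- suppressWarnings(summarize_groups(pk, by = "peak"))
  h <- pooled[pooled$group == "a" & pooled$metric == "height_pct", ]
  expect_equal(h$mean, 20)
  expect_equal(h$n, 2)
  expect_warning(summarize_groups(pk), "no peaks")
  one <- suppressWarnings(summarize_groups(pk[3, ], by = "recording"))
  expect_equal(one$mean[one$metric == "height_pct"], 20)
})
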