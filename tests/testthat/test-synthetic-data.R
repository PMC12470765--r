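test_that("recording geometry follows the acquisition protocol", {
  sim <- simulate_fret_recording(NULL, duration = 900, rate = 2.5, seed = 1)
  expect_equal(nrow(sim$recording), 2250)
  expect_equal(sim$recording$time_s[2] - sim$recording$time_s[1], 0.4)
})

test_that("a spec with no transients, noise or bleach gives constant channels", {
  sim <- simulate_fret_recording(NULL, duration = 100, noise_sd = 0,
                                 bleach_rate = 0, seed = 1)
  expect_true(all(sim$recording$f480 == sim$recording$f480[1]))
  expect_true(all(sim$recording$f535 == sim$recording$f535[1]))
  ratio <- sim$recording$f535 / sim$recording$f480
  expect_true(all(ratio == ratio[1]))
  expect_equal(nrow(sim$truth), 0)
})

test_that("generators are pure functions of spec and seed", {
  tr <- transient_spec(t0 = c(50, 150), A = 0.1)
  a <- simulate_fret_recording(tr, duration = 300, seed = 42)
  b <- simulate_fret_recording(tr, duration = 300, seed = 42)
  expect_identical(a$recording, b$recording)
  m1 <- generate_mito_mask(gap_prob = 0.3, jitter_sd = 1, seed = 7)
  m2 <- generate_mito_mask(gap_prob = 0.3, jitter_sd = 1, seed = 7)
  expect_identical(m1$mask, m2$mask)
  g1 <- generate_aggregate_image(seed = 9)
  g2 <- generate_aggregate_image(seed = 9)
  expect_identical(g1$image, g2$image)
})

test_that("shared bleaching cancels exactly in the noise-free ratio", {
  tr <- transient_spec(t0 = 30, A = 0.2)
  a <- simulate_fret_recording(tr, duration = 120, noise_sd = 0,
                               bleach_rate = 0, seed = 1)
  b <- simulate_fret_recording(tr, duration = 120, noise_sd = 0,
                               bleach_rate = 0.002, seed = 1)
  expect_equal(b$recording$f535 / b$recording$f480,
               a$recording$f535 / a$recording$f480, tolerance = 1e-12)
})

test_that("overlapping transients are rejected with an explicit error", {
  tr <- transient_spec(t0 = c(100, 101), A = 0.1, tau_rise = 1,
                       tau_decay = 5)
  expect_error(simulate_fret_recording(tr, duration = 300),
               "overlapping")
  expect_error(simulate_fret_recording(NULL, duration = -1), "duration")
  expect_error(simulate_fret_recording(NULL, rate = 0), "rate")
})

test_that("transient and artifact segments have opposite channel coupling", {
  tr <- transient_spec(t0 = 60, A = 0.15)
  art <- transient_spec(t0 = 200, A = 0.15)
  sim <- simulate_fret_recording(tr, artifacts = art, duration = 300,
                                 noise_sd = 0.002, seed = 5)
  rec <- sim$recording
  seg_cor <- function(t1, t2) {
    i <- rec$time_s >= t1 & rec$time_s <= t2
    t <- rec$time_s[i]
    cor(resid(lm(rec$f535[i] ~ t)), resid(lm(rec$f480[i] ~ t)))
  }
  expect_lt(seg_cor(58, 90), -0.8)   # true transient: mirror change
  expect_gt(seg_cor(198, 230), 0.8)  # artifact: same-sign change
})

test_that("oracle metrics reject a zero-amplitude kernel and respect symmetry", {
  expect_error(
    transient_oracle_metrics(tibble::tibble(t0 = 0, A = 0, tau_rise = 1,
                                            tau_decay = 5, shape = "dblexp")),
    "no transient")
  o <- transient_oracle_metrics(
    transient_spec(t0 = 10, A = 0.2, tau_rise = 2, tau_decay = 2.0000001,
                   shape = "triangle"))
  expect_equal(o$rise_time_s, o$decay_time_s, tolerance = 1e-3)
  expect_equal(o$rise_rate_pct_per_s, o$decay_rate_pct_per_s,
               tolerance = 1e-3)
})

test_that("oracle half-height width matches an independent dense-grid brute force", {
  # independent route: flat loop over an even finer grid, nearest-sample
  # crossings (no interpolation), for a double-exponential kernel whose
  # apex ratio change is ~50%
  A <- 0.2  # ratio height = (1.2/0.8 - 1) = 50%
  tau_r <- 1; tau_d <- 5; t0 <- 0
  dt <- 1e-4
  tt <- seq(0, 60, by = dt)
  u_peak <- tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
  norm <- exp(-u_peak / tau_d) - exp(-u_peak / tau_r)
  s <- A * (exp(-tt / tau_d) - exp(-tt / tau_r)) / norm
  r <- (1 + s) / (1 - s)
  lev <- 1 + 0.5 * (max(r) - 1)
  above <- which(r >= lev)
  brute_width <- (max(above) - min(above)) * dt
  o <- transient_oracle_metrics(transient_spec(t0 = t0, A = A,
                                               tau_rise = tau_r,
                                               tau_decay = tau_d))
  expect_equal(o$half_height_width_s, brute_width, tolerance = 1e-3)
  expect_equal(o$height_pct, 100 * (max(r) - 1), tolerance = 1e-4)
})

test_that("mito mask expectation and degenerate cases follow the closed form", {
  full <- generate_mito_mask(gap_prob = 0, inter_unit_gap = 0, seed = 1)
  expect_equal(full$expected_coverage, 1)
  expect_true(all(full$mask == 1))
  empty <- generate_mito_mask(gap_prob = 1, seed = 1)
  expect_true(all(empty$mask == 0))
  expect_equal(empty$expected_coverage, 0)
  g <- generate_mito_mask(gap_prob = 0.25, inter_unit_gap = 5,
                          unit_length = 20, seed = 1)
  expect_equal(g$expected_coverage, 0.75 * 20 / 25)
  expect_error(generate_mito_mask(image_shape = c(40, 150)), "200")
  expect_error(generate_mito_mask(gap_prob = 2), "gap_prob")
})

test_that("mean line coverage decreases with gap_prob on a fixed seed ladder", {
  ladder <- seq(0, 0.9, by = 0.1)
  cover <- vapply(ladder, function(g) {
    gen <- generate_mito_mask(n_rows = 30, gap_prob = g,
                              inter_unit_gap = 0, seed = 11)
    assess_linearity(gen$mask, n_lines = 200, seed = 12)$percent_coverage
  }, numeric(1))
  expect_true(all(diff(cover) <= 0))
})

test_that("aggregate image truth is an identity on the label image", {
  z <- generate_aggregate_image(n_aggregates = 0, seed = 1)
  expect_equal(z$truth$fraction, 0)
  g <- generate_aggregate_image(n_aggregates = 3, radii = 5, seed = 4)
  expect_equal(g$truth$fraction,
               sum(g$labels == 2) / sum(g$labels > 0))
  expect_equal(g$truth$total_aggregate_area, sum(g$labels == 2))
  expect_equal(g$truth$worm_area, sum(g$labels > 0))
})

test_that("explicit disk placement matches brute-force rasterization", {
  ctr <- rbind(c(96, 80), c(96, 110), c(60, 96))
  g <- generate_aggregate_image(n_aggregates = 3, radii = 5, centers = ctr,
                                noise_sd = 0, seed = 1)
  # brute force: count pixels whose center lies within radius of a center
  nr <- nrow(g$image); nc <- ncol(g$image)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  painted <- matrix(FALSE, nr, nc)
  for (i in 1:3) {
    painted <- painted | ((rr - ctr[i, 1])^2 + (cc - ctr[i, 2])^2 <= 25)
  }
  expect_equal(g$truth$total_aggregate_area, sum(painted))
  expect_error(
    generate_aggregate_image(n_aggregates = 1, radii = 5,
                             centers = rbind(c(5, 5)), seed = 1),
    "outside the worm")
})
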