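#' Analysis configuration for Ca2+ transient detection
#'
#' The published algorithm is described only qualitatively (identify peaks
#' by mirror changes in both wavelengths, then measure per-peak kinetics),
#' so the operational parameters live here and are all user-visible.
#'
#' @param baseline_window_s Width of the sliding window (seconds) for the
#'   running low-percentile baseline (default 60 s).
#' @param baseline_prob Percentile used for the baseline (default 0.1, the
#'   10th percentile: insensitive to transients occupying under half of a
#'   window).
#' @param k Prominence threshold as a multiple of the robust noise SD
#'   (default 4).
#' @param mirror_threshold Maximum Pearson correlation (negative) of the
#'   detrended channels for a candidate to be accepted as a true Ca2+ peak
#'   (default -0.5).
#' @param eps Boundary fraction of peak height: a peak starts/ends where the
#'   ratio re-enters `baseline + eps * height` (default 0.1, must be in
#'   (0, 0.5)).
#' @param min_sep_s Minimum separation between accepted apexes in seconds.
#' @param smooth_s Width (seconds) of the centered moving average applied
#'   to the ratio before baseline estimation and peak detection inside
#'   [analyze_recording()] (default 2 s, i.e. 5 frames at 2.5 Hz). Light
#'   smoothing keeps single-sample noise excursions from masquerading as
#'   peaks while widening a multi-second transient only marginally. Set to
#'   0 to disable.
#' @return A list of class `ca_config`.
#' @export
analysis_config <- function(baseline_window_s = 60, baseline_prob = 0.1,
                            k = 4, mirror_threshold = -0.5, eps = 0.1,
                            min_sep_s = 2, smooth_s = 2) {
  if (k <= 0) abort("`k` must be positive.")
  if (mirror_threshold >= 0 || mirror_threshold < -1) {
    abort("`mirror_threshold` must lie in [-1, 0).")
  }
  if (eps <= 0 || eps >= 0.5) abort("`eps` must lie in (0, 0.5).")
  if (smooth_s < 0) abort("`smooth_s` must be >= 0.")
  structure(list(baseline_window_s = baseline_window_s,
                 baseline_prob = baseline_prob, k = k,
                 mirror_threshold = mirror_threshold, eps = eps,
                 min_sep_s = min_sep_s, smooth_s = smooth_s),
            class = "ca_config")
}

validate_recording <- function(rec) {
  need <- c("time_s", "f480", "f535")
  if (!is.data.frame(rec) || !all(need %in% names(rec))) {
    abort("a recording needs columns time_s, f480, f535.")
  }
  if (nrow(rec) < 2) abort("a recording needs at least 2 samples.")
  if (any(diff(rec$time_s) <= 0)) abort("time_s must be strictly increasing.")
  invisible(rec)
}

#' Compute the acceptor/donor fluorescence ratio trace
#'
#' Point-wise `F535 / F480`. Because photobleaching and excitation
#' fluctuations scale both emission channels by the same factor, they cancel
#' in the ratio, which is why the ratio (not either channel) carries the
#' Ca2+ signal.
#'
#' @param rec A recording tibble with columns `time_s`, `f480`, `f535`.
#' @return A tibble `time_s`, `ratio` (with a `baseline` column of `NA`
#'   until [estimate_baseline()] fills it).
#' @export
compute_ratio <- function(rec) {
  validate_recording(rec)
  if (any(rec$f480 <= 0)) abort("f480 must be positive to form the ratio.")
  tibble(time_s = rec$time_s, ratio = rec$f535 / rec$f480,
         baseline = NA_real_)
}

#' Estimate the resting-ratio baseline
#'
#' Sliding low-percentile of the ratio (default: 10th percentile over a
#' 60 s window), then smoothed with a running mean of the same width.
#' A low percentile tracks the resting level even through transients, as
#' long as no single window is majority-occupied by transients. On a noisy
#' trace the p-th percentile of resting noise sits `qnorm(p) * sigma` below
#' the resting mean; that known offset is added back (`sigma` being the
#' robust per-sample noise SD), so the estimator is unbiased for the
#' resting level. For a noise-free trace the correction is exactly zero.
#'
#' @param trace Ratio trace from [compute_ratio()].
#' @param cfg An [analysis_config()].
#' @param sigma Per-sample noise SD of `trace$ratio` used for the
#'   percentile-bias correction; estimated robustly from the trace when
#'   `NULL`.
#' @return The trace with its `baseline` column filled.
#' @export
estimate_baseline <- function(trace, cfg = analysis_config(), sigma = NULL) {
  dt <- median(diff(trace$time_s))
  w <- max(10L, round(cfg$baseline_window_s / dt))
  if (w > nrow(trace)) abort("baseline window longer than the recording.")
  if (w %% 2 == 0) w <- w + 1L
  if (is.null(sigma)) sigma <- robust_noise_sd(trace$ratio)
  b <- sliding_quantile(trace$ratio, w, cfg$baseline_prob)
  b <- zoo::rollapply(b, width = w, FUN = mean, partial = TRUE,
                      align = "center")
  trace$baseline <- b - stats::qnorm(cfg$baseline_prob) * sigma
  trace
}

# Robust per-sample noise SD from first differences: for white noise of SD
# sigma, |diff| has median sigma*sqrt(2)/1.4826^-1, hence the constants.
# Transients contribute few large differences and are ignored by the median.
robust_noise_sd <- function(ratio) {
  1.4826 * median(abs(diff(ratio))) / sqrt(2)
}

# Topographic prominence of local maxima of x: height above the higher of
# the two minima separating the peak from the nearest higher ground (or the
# record edge).
peak_prominence <- function(x, apexes) {
  vapply(apexes, function(i) {
    left <- if (i > 1) {
      higher <- which(x[seq_len(i - 1)] > x[i])
      lo <- if (length(higher)) max(higher) + 1L else 1L
      min(x[lo:(i - 1L)])
    } else x[i]
    right <- if (i < length(x)) {
      seg <- x[(i + 1L):length(x)]
      higher <- which(seg > x[i])
      hi <- if (length(higher)) i + min(higher) - 1L else length(x)
      min(x[(i + 1L):hi])
    } else x[i]
    x[i] - max(left, right)
  }, numeric(1))
}

#' Detect candidate Ca2+ peak intervals on a ratio trace
#'
#' Candidate apexes are local maxima of `ratio - baseline` whose topographic
#' prominence is at least `k` times the robust noise SD (estimated from the
#' median absolute first difference, which is blind to sparse transients).
#' Interval boundaries are placed where the excess ratio re-enters
#' `eps * height`, or at the trough separating two adjacent peaks;
#' intervals are non-overlapping and time-ordered. No mirror filtering is
#' applied here -- that is [mirror_change_score()]'s job.
#'
#' @param trace Ratio trace with baseline (see [estimate_baseline()]).
#' @param cfg An [analysis_config()].
#' @param sigma Noise SD defining the prominence threshold `k * sigma`;
#'   estimated robustly from the trace when `NULL`. [analyze_recording()]
#'   passes the raw (pre-smoothing) ratio noise SD so the threshold is
#'   expressed in raw noise units even though detection runs on the
#'   smoothed trace.
#' @return Tibble of candidate intervals: index columns `i_start`, `i_apex`,
#'   `i_end` and their times `t_start`, `t_apex`, `t_end`, plus `prominence`
#'   and the noise estimate `sigma` (same for all rows).
#' @export
detect_peaks <- function(trace, cfg = analysis_config(), sigma = NULL) {
  if (all(is.na(trace$baseline))) abort("baseline not estimated yet.")
  d <- trace$ratio - trace$baseline
  n <- length(d)
  if (is.null(sigma)) sigma <- robust_noise_sd(trace$ratio)
  empty <- tibble(i_start = integer(), i_apex = integer(), i_end = integer(),
                  t_start = numeric(), t_apex = numeric(), t_end = numeric(),
                  prominence = numeric(), sigma = numeric())
  if (sigma == 0 && all(d == d[1])) return(empty)
  # strict-right local maxima; plateau ties resolve to the earliest sample
  apex <- which(d > c(-Inf, head(d, -1)) & d >= c(tail(d, -1), Inf))
  apex <- apex[apex > 1 & apex < n]
  if (!length(apex)) return(empty)
  prom <- peak_prominence(d, apex)
  # floor guards against float ripple on analytically constant ratios
  thr <- max(cfg$k * sigma, 1e-9 * median(trace$ratio))
  keep <- prom >= thr
  apex <- apex[keep]; prom <- prom[keep]
  if (!length(apex)) return(empty)
  # enforce minimum apex separation, keeping the taller peak
  ord <- order(d[apex], decreasing = TRUE)
  sel <- logical(length(apex))
  taken <- numeric(0)
  for (j in ord) {
    tj <- trace$time_s[apex[j]]
    if (!length(taken) || all(abs(taken - tj) >= cfg$min_sep_s)) {
      sel[j] <- TRUE
      taken <- c(taken, tj)
    }
  }
  apex <- apex[sel]; prom <- prom[sel]
  o <- order(apex)
  apex <- apex[o]; prom <- prom[o]
  # boundaries: walk out from the apex until d <= eps * height, clipped at
  # the trough shared with the neighbouring accepted peak
  m <- length(apex)
  i_start <- integer(m); i_end <- integer(m)
  for (j in seq_len(m)) {
    h <- d[apex[j]]
    lev <- cfg$eps * h
    lo_lim <- if (j > 1) apex[j - 1] else 1L
    i <- apex[j]
    while (i > lo_lim && d[i - 1] > lev) i <- i - 1L
    i_start[j] <- i - (i > lo_lim)
    hi_lim <- if (j < m) apex[j + 1] else n
    i <- apex[j]
    while (i < hi_lim && d[i + 1] > lev) i <- i + 1L
    i_end[j] <- i + (i < hi_lim)
  }
  # split any overlap between neighbours at the inter-peak trough
  for (j in seq_len(m - 1)) {
    if (i_end[j] >= i_start[j + 1]) {
      tr_i <- apex[j] + which.min(d[(apex[j] + 1):(apex[j + 1] - 1)])
      i_end[j] <- tr_i
      i_start[j + 1] <- tr_i
    }
  }
  tibble(i_start = i_start, i_apex = apex, i_end = i_end,
         t_start = trace$time_s[i_start], t_apex = trace$time_s[apex],
         t_end = trace$time_s[i_end], prominence = prom, sigma = sigma)
}

#' Mirror-change score of a candidate interval
#'
#' A true Ca2+ transient raises the acceptor (535 nm) emission while
#' lowering the donor (480 nm) emission; artifacts (focus drift, motion,
#' bleaching steps) move both channels in the same direction. The score is
#' the Pearson correlation of the two linearly detrended channels over the
#' interval: -1 for a perfect mirror change, +1 for a same-sign artifact.
#' With `smooth > 1` the channels are first averaged over a short centered
#' window so the score reflects the event waveform rather than per-frame
#' shot noise (frame noise is uncorrelated between channels and only
#' dilutes the correlation of a genuine mirror event). A sign check is
#' also reported: relative to the interval edges, the acceptor must rise
#' and the donor fall around the apex.
#'
#' @param rec Recording tibble (`time_s`, `f480`, `f535`).
#' @param i_start,i_apex,i_end Sample indices of the interval.
#' @param smooth Width in samples of the centered moving average applied to
#'   each channel before correlating (1 = none). [analyze_recording()]
#'   passes its ratio-smoothing width.
#' @return A list with `score` (in `[-1, 1]`), `sign_ok` (logical), and the
#'   per-channel apex-minus-edge deltas `d535`, `d480`.
#' @export
mirror_change_score <- function(rec, i_start, i_apex, i_end, smooth = 1) {
  idx <- i_start:i_end
  if (length(idx) < 3) abort("interval must span at least 3 samples.")
  t <- rec$time_s[idx]
  y5 <- rec$f535[idx]; y4 <- rec$f480[idx]
  if (smooth > 1) {
    y5 <- zoo::rollapply(y5, width = smooth, FUN = mean, partial = TRUE,
                         align = "center")
    y4 <- zoo::rollapply(y4, width = smooth, FUN = mean, partial = TRUE,
                         align = "center")
  }
  if (sd(y5) == 0 || sd(y4) == 0) {
    abort("mirror score undefined: a channel is constant on the interval.")
  }
  r5 <- resid(lm(y5 ~ t)); r4 <- resid(lm(y4 ~ t))
  if (sd(r5) == 0 || sd(r4) == 0) {
    abort("mirror score undefined: a channel is linear on the interval.")
  }
  score <- cor(r5, r4)
  edge <- (rec$f535[i_start] + rec$f535[i_end]) / 2
  d535 <- rec$f535[i_apex] - edge
  edge4 <- (rec$f480[i_start] + rec$f480[i_end]) / 2
  d480 <- rec$f480[i_apex] - edge4
  list(score = score, sign_ok = d535 > 0 && d480 < 0,
       d535 = d535, d480 = d480)
}

#' Measure the kinetics of one accepted peak
#'
#' Reports, for the given interval, the quantities of the published
#' protocol: height as a percentage of ratio change from base to peak,
#' total width and width at half-height in seconds, time to rise from base
#' to peak and time to return to base, and the derived rates
#' (rise rate = height / time-to-peak, decay rate = height / decay time).
#' Half-height crossing times are linearly interpolated between samples.
#'
#' @param trace Ratio trace with baseline.
#' @param i_start,i_apex,i_end Sample indices of the accepted interval.
#' @return One-row tibble of peak metrics.
#' @export
measure_peak <- function(trace, i_start, i_apex, i_end) {
  if (i_end - i_start < 2) abort("interval must span at least 3 samples.")
  stopifnot(i_start < i_apex, i_apex < i_end)
  t <- trace$time_s; r <- trace$ratio
  base <- trace$baseline[i_apex]
  h <- r[i_apex] - base
  if (h <= 0) abort("non-positive height: apex does not exceed baseline.")
  level <- base + 0.5 * h
  # last upward crossing of the half level before the apex
  pre <- i_start:i_apex
  below <- pre[r[pre] < level]
  if (!length(below)) {
    t1 <- t[i_start]
  } else {
    i1 <- max(below)
    t1 <- t[i1] + (t[i1 + 1] - t[i1]) * (level - r[i1]) / (r[i1 + 1] - r[i1])
  }
  post <- i_apex:i_end
  below <- post[r[post] < level]
  if (!length(below)) {
    t2 <- t[i_end]
  } else {
    i2 <- min(below)
    t2 <- t[i2 - 1] + (t[i2] - t[i2 - 1]) * (level - r[i2 - 1]) /
      (r[i2] - r[i2 - 1])
  }
  rise <- t[i_apex] - t[i_start]
  decay <- t[i_end] - t[i_apex]
  hp <- 100 * h / base
  tibble(t_start = t[i_start], t_apex = t[i_apex], t_end = t[i_end],
         baseline_ratio = base, height_pct = hp,
         total_width_s = t[i_end] - t[i_start],
         half_height_width_s = t2 - t1,
         rise_time_s = rise, decay_time_s = decay,
         rise_rate_pct_per_s = hp / rise,
         decay_rate_pct_per_s = hp / decay)
}

#' Analyze a dual-channel recording end to end
#'
#' Runs the full trace pipeline: ratio, light smoothing (`cfg$smooth_s`),
#' baseline, candidate detection, per-candidate mirror-change filtering,
#' and kinetic measurement of each accepted peak. Detection and
#' measurement operate on the smoothed ratio with the prominence threshold
#' expressed in raw-noise units; smoothing is linear in the ratio, so the
#' bleach-cancellation property of the ratio is untouched. Candidates touching the first or last sample of the
#' record are discarded (their kinetics would be truncated) and counted in
#' `n_edge_discarded`. The whole chain is deterministic.
#'
#' @param rec Recording tibble (`time_s`, `f480`, `f535`).
#' @param cfg An [analysis_config()].
#' @return An object of class `ca_analysis`: list with `peaks` (tibble, one
#'   row per accepted peak, including `mirror_score`), `candidates`
#'   (detected intervals before filtering), `summary` (one-row tibble of
#'   peak-metric means and SEMs), `n_edge_discarded`, `sigma`, and `cfg`.
#' @export
#' @examples
#' sim <- simulate_fret_recording(transient_spec(t0 = c(100, 200)),
#'                                duration = 400, seed = 2)
#' fit <- analyze_recording(sim$recording)
#' fit$summary
analyze_recording <- function(rec, cfg = analysis_config()) {
  validate_recording(rec)
  trace <- compute_ratio(rec)
  dt <- median(diff(trace$time_s))
  sigma_raw <- robust_noise_sd(trace$ratio)
  m <- max(1L, round(cfg$smooth_s / dt))
  if (m %% 2 == 0) m <- m + 1L
  if (m > 1L) {
    trace$ratio <- zoo::rollapply(trace$ratio, width = m, FUN = mean,
                                  partial = TRUE, align = "center")
  }
  # after an m-point boxcar the per-sample noise SD shrinks by sqrt(m)
  trace <- estimate_baseline(trace, cfg, sigma = sigma_raw / sqrt(m))
  cand <- detect_peaks(trace, cfg, sigma = sigma_raw)
  n <- nrow(trace)
  edge <- cand$i_start <= 1L | cand$i_end >= n
  n_edge <- sum(edge)
  cand <- cand[!edge, , drop = FALSE]
  peaks <- purrr::pmap(cand, function(i_start, i_apex, i_end, ...) {
    if (i_end - i_start < 2) return(NULL)
    ms <- tryCatch(mirror_change_score(rec, i_start, i_apex, i_end,
                                       smooth = m),
                   error = function(e) NULL)
    if (is.null(ms)) return(NULL)
    if (!(ms$score <= cfg$mirror_threshold && ms$sign_ok)) return(NULL)
    pk <- tryCatch(measure_peak(trace, i_start, i_apex, i_end),
                   error = function(e) NULL)
    if (is.null(pk)) return(NULL)
    pk$mirror_score <- ms$score
    pk
  })
  peaks <- dplyr::bind_rows(peaks)
  if (nrow(peaks) == 0) {
    peaks <- measure_peak(
      tibble(time_s = c(0, 1, 2), ratio = c(1, 2, 1), baseline = 1),
      1L, 2L, 3L)[0, ]
    peaks$mirror_score <- numeric(0)
  }
  structure(list(peaks = peaks, candidates = cand,
                 summary = summarize_peaks(peaks),
                 n_edge_discarded = n_edge,
                 sigma = sigma_raw,
                 trace = trace, cfg = cfg),
            class = "ca_analysis")
}

summarize_peaks <- function(peaks) {
  metrics <- c("height_pct", "half_height_width_s", "total_width_s",
               "rise_rate_pct_per_s", "decay_rate_pct_per_s")
  out <- tibble(n_peaks = nrow(peaks))
  for (m in metrics) {
    out[[paste0("mean_", m)]] <- if (nrow(peaks)) mean(peaks[[m]]) else NA_real_
    out[[paste0("sem_", m)]] <- sem(peaks[[m]])
  }
  out
}

#' @export
print.ca_analysis <- function(x, ...) {
  cat("<ca_analysis> ", nrow(x$peaks), " accepted peak(s), ",
      nrow(x$candidates) - nrow(x$peaks), " candidate(s) rejected, ",
      x$n_edge_discarded, " edge-truncated\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Summarize peak metrics across groups of recordings
#'
#' Aggregates per-peak metrics over labelled recordings, either pooling all
#' peaks within a group (`by = "peak"`, matching figure-style
#' "n = peaks analyzed" reporting) or first averaging within each
#' recording and then across recordings (`by = "recording"`). Groups that
#' contributed no peaks are dropped with a warning rather than reported as
#' zero.
#'
#' @param peaks A tibble of peaks carrying at least the metric columns plus
#'   `group` and `recording_id` columns (build it by row-binding
#'   `fit$peaks` of several [analyze_recording()] results).
#' @param by `"peak"` (pool) or `"recording"` (per-worm means first).
#' @return A tibble with one row per group and metric: `n`, `mean`, `sem`.
#' @export
summarize_groups <- function(peaks, by = c("peak", "recording")) {
  by <- match.arg(by)
  need <- c("group", "recording_id")
  if (!all(need %in% names(peaks))) {
    abort("`peaks` needs 'group' and 'recording_id' columns.")
  }
  metrics <- intersect(c("height_pct", "half_height_width_s",
                         "total_width_s", "rise_time_s", "decay_time_s",
                         "rise_rate_pct_per_s", "decay_rate_pct_per_s"),
                       names(peaks))
  long <- tidyr::pivot_longer(peaks[, c(need, metrics)],
                              dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  if (by == "recording") {
    long <- dplyr::summarise(
      dplyr::group_by(long, .data$group, .data$recording_id, .data$metric),
      value = mean(.data$value), .groups = "drop")
  }
  out <- dplyr::summarise(dplyr::group_by(long, .data$group, .data$metric),
                          n = dplyr::n(), mean = mean(.data$value),
                          sem = sem(.data$value), .groups = "drop")
  all_groups <- if (is.factor(peaks$group)) levels(peaks$group)
                else unique(peaks$group)
  missing <- setdiff(all_groups, unique(as.character(out$group)))
  if (length(missing)) {
    warn(paste("groups with no peaks excluded:",
               paste(missing, collapse = ", ")))
  }
  out
}
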