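#' Build a table of transient (or artifact) specifications
#'
#' A transient is described by its onset time, peak fractional channel
#' modulation and kinetic time constants. Two kernel shapes are available:
#' `"dblexp"`, the standard double-exponential Ca2+ transient phenomenology
#' `A * (exp(-u/tau_decay) - exp(-u/tau_rise)) / max`, normalized so the peak
#' modulation is exactly `A`; and `"triangle"`, a piecewise-linear pulse
#' (linear rise over `tau_rise` seconds, linear return over `tau_decay`
#' seconds) whose kinetic metrics have closed forms, used for exact tests.
#'
#' @param t0 Onset time(s) in seconds (>= 0).
#' @param A Peak fractional modulation of each emission channel (> 0,
#'   dimensionless). The acceptor is modulated by `(1 + s)`, the donor by
#'   `(1 - s)`, so the FRET ratio rises by about `2A` at the apex.
#' @param tau_rise,tau_decay Rise and decay time constants in seconds
#'   (`dblexp`) or rise/decay durations (`triangle`); `tau_rise < tau_decay`.
#' @param shape `"dblexp"` or `"triangle"`.
#' @return A tibble with one row per transient.
#' @export
#' @examples
#' transient_spec(t0 = c(100, 300), A = 0.1, tau_rise = 1, tau_decay = 5)
transient_spec <- function(t0, A = 0.1, tau_rise = 1, tau_decay = 5,
                           shape = "dblexp") {
  out <- tibble(t0 = t0, A = A, tau_rise = tau_rise,
                tau_decay = tau_decay, shape = shape)
  validate_transients(out)
  out
}

validate_transients <- function(tr) {
  if (is.null(tr) || nrow(tr) == 0) return(invisible(tr))
  need <- c("t0", "A", "tau_rise", "tau_decay")
  if (!all(need %in% names(tr))) {
    abort("transient table needs columns t0, A, tau_rise, tau_decay.")
  }
  if (!"shape" %in% names(tr)) tr$shape <- "dblexp"
  if (any(tr$t0 < 0)) abort("transient onset t0 must be >= 0.")
  if (any(tr$A < 0)) abort("transient amplitude A must be >= 0.")
  if (any(tr$tau_rise <= 0 | tr$tau_decay <= 0)) {
    abort("transient time constants must be positive.")
  }
  if (any(tr$tau_rise >= tr$tau_decay)) {
    abort("transients require tau_rise < tau_decay.")
  }
  if (!all(tr$shape %in% c("dblexp", "triangle"))) {
    abort("transient shape must be 'dblexp' or 'triangle'.")
  }
  invisible(tr)
}

# Evaluate one transient kernel at times t (vectorized, zero before onset).
kernel_value <- function(t, t0, A, tau_rise, tau_decay, shape = "dblexp") {
  u <- t - t0
  s <- numeric(length(t))
  on <- u >= 0
  if (shape == "triangle") {
    up <- on & u <= tau_rise
    dn <- on & u > tau_rise & u <= tau_rise + tau_decay
    s[up] <- A * u[up] / tau_rise
    s[dn] <- A * (1 - (u[dn] - tau_rise) / tau_decay)
  } else {
    u_peak <- tau_rise * tau_decay / (tau_decay - tau_rise) *
      log(tau_decay / tau_rise)
    norm <- exp(-u_peak / tau_decay) - exp(-u_peak / tau_rise)
    s[on] <- A * (exp(-u[on] / tau_decay) - exp(-u[on] / tau_rise)) / norm
  }
  s
}

# Effective kernel width: time from onset until the kernel has decayed
# below frac * A. Used for the transient-overlap guard.
kernel_width <- function(A, tau_rise, tau_decay, shape = "dblexp",
                         frac = 0.01) {
  if (shape == "triangle") return(tau_rise + tau_decay)
  u_peak <- tau_rise * tau_decay / (tau_decay - tau_rise) *
    log(tau_decay / tau_rise)
  norm <- exp(-u_peak / tau_decay) - exp(-u_peak / tau_rise)
  # beyond the apex the kernel is dominated by the decay exponential
  max(u_peak, -tau_decay * log(frac * norm))
}

sum_kernels <- function(time, tr) {
  if (is.null(tr) || nrow(tr) == 0) return(numeric(length(time)))
  validate_transients(tr)
  if (!"shape" %in% names(tr)) tr$shape <- "dblexp"
  s <- numeric(length(time))
  for (i in seq_len(nrow(tr))) {
    s <- s + kernel_value(time, tr$t0[i], tr$A[i], tr$tau_rise[i],
                          tr$tau_decay[i], tr$shape[i])
  }
  s
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Ground-truth kinetic metrics of a transient kernel by dense-grid brute force
#'
#' Computes, independently of the trace-analysis pipeline, the kinetic
#' metrics a perfect analysis would report for each noise-free transient:
#' the FRET ratio implied by a channel modulation `s` is
#' `ratio_fun(s)` (default `(1 + s) / (1 - s)`, the ratio of an acceptor
#' scaled by `1 + s` and a donor scaled by `1 - s`), evaluated on a grid
#' hundreds of times finer than the camera frame interval. Peak start/end
#' are where the ratio re-enters `baseline + eps * height`; half-height
#' crossings are linearly interpolated on the dense grid.
#'
#' @param transients Tibble from [transient_spec()].
#' @param ratio_fun Mapping from summed kernel modulation to ratio.
#' @param eps Boundary fraction of peak height defining start/end.
#' @param grid_dt Dense-grid step in seconds (default 1/2500 s, i.e. 1000x
#'   finer than the 2.5 Hz frame rate).
#' @return A tibble with one row per transient: apex/boundary times,
#'   `height_pct`, widths, rise/decay times and rates.
#' @export
transient_oracle_metrics <- function(transients,
                                     ratio_fun = function(s) (1 + s) / (1 - s),
                                     eps = 0.1, grid_dt = 1 / 2500) {
  validate_transients(transients)
  if (any(transients$A == 0)) abort("no transient: amplitude A is zero.")
  base <- ratio_fun(0)
  rows <- purrr::pmap(transients, function(t0, A, tau_rise, tau_decay,
                                           shape = "dblexp", ...) {
    w <- kernel_width(A, tau_rise, tau_decay, shape, frac = 1e-4)
    tt <- seq(t0, t0 + w, by = grid_dt)
    r <- ratio_fun(kernel_value(tt, t0, A, tau_rise, tau_decay, shape))
    i_apex <- which.max(r)  # earliest index on ties
    h <- r[i_apex] - base
    cross <- function(level) {
      # rising-edge crossing before the apex, falling-edge after
      pre <- r[seq_len(i_apex)]
      i1 <- max(which(pre < level))
      t1 <- tt[i1] + grid_dt * (level - r[i1]) / (r[i1 + 1] - r[i1])
      post <- r[i_apex:length(r)]
      i2 <- i_apex - 1 + min(which(post < level))
      t2 <- tt[i2 - 1] + grid_dt * (level - r[i2 - 1]) / (r[i2] - r[i2 - 1])
      c(t1, t2)
    }
    b <- cross(base + eps * h)
    hh <- cross(base + 0.5 * h)
    rise <- tt[i_apex] - b[1]
    decay <- b[2] - tt[i_apex]
    tibble(t0 = t0, t_start = b[1], t_apex = tt[i_apex], t_end = b[2],
           baseline_ratio = base, height_pct = 100 * h / base,
           total_width_s = b[2] - b[1], half_height_width_s = hh[2] - hh[1],
           rise_time_s = rise, decay_time_s = decay,
           rise_rate_pct_per_s = 100 * h / base / rise,
           decay_rate_pct_per_s = 100 * h / base / decay)
  })
  dplyr::bind_rows(rows)
}

#' Simulate a dual-emission ratiometric FRET recording
#'
#' Generates a two-channel cameleon-style recording in which each Ca2+
#' transient modulates the acceptor (535 nm) and donor (480 nm) channels in
#' opposite directions -- the mirror-image signature of a true cytosolic
#' Ca2+ change -- while photobleaching decays both channels by a shared
#' exponential and motion/focus artifacts move both channels in the same
#' direction (with unequal per-channel gains, so artifacts do perturb the
#' ratio and must be rejected downstream by the mirror criterion).
#'
#' The noise-free model at time `t` with summed transient modulation `s(t)`
#' and summed artifact modulation `a(t)` is
#' \deqn{F535 = f535\_base\, e^{-bleach\, t} (1 + s + g_{535} a)(1+\epsilon_1)}
#' \deqn{F480 = f480\_base\, e^{-bleach\, t} (1 - s + g_{480} a)(1+\epsilon_2)}
#' with independent white Gaussian `eps` of standard deviation `noise_sd`.
#'
#' @param transients Tibble from [transient_spec()] (may be `NULL`/empty).
#' @param duration Recording length in seconds (default 900 = 15 min).
#' @param rate Frame rate in Hz (default 2.5).
#' @param f480_base,f535_base Baseline fluorescence (a.u.).
#' @param noise_sd Gaussian noise SD as a fraction of baseline.
#' @param bleach_rate Shared exponential bleaching constant (1/s).
#' @param artifacts Tibble from [transient_spec()] describing same-sign
#'   artifact events, or `NULL`.
#' @param artifact_gain Length-2 named numeric `c(f535 = , f480 = )`:
#'   per-channel gains applied to the artifact modulation (both positive).
#' @param seed Integer seed; the same spec and seed give bit-identical
#'   output.
#' @return A list with `recording` (tibble `time_s`, `f480`, `f535`) and
#'   `truth` (oracle peak metrics from [transient_oracle_metrics()], empty
#'   tibble when there are no transients).
#' @export
#' @examples
#' sim <- simulate_fret_recording(transient_spec(t0 = 100), duration = 300,
#'                                seed = 1)
#' head(sim$recording)
simulate_fret_recording <- function(transients = NULL, duration = 900,
                                    rate = 2.5, f480_base = 100,
                                    f535_base = 100, noise_sd = 0.01,
                                    bleach_rate = 0, artifacts = NULL,
                                    artifact_gain = c(f535 = 1, f480 = 0.6),
                                    seed = 1) {
  if (duration <= 0) abort("`duration` must be positive.")
  if (rate <= 0) abort("`rate` must be positive.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (bleach_rate < 0) abort("`bleach_rate` must be >= 0.")
  if (any(artifact_gain <= 0)) abort("artifact gains must be positive.")
  validate_transients(transients)
  validate_transients(artifacts)
  if (!is.null(transients) && nrow(transients) > 1) {
    tr <- dplyr::arrange(transients, .data$t0)
    if (!"shape" %in% names(tr)) tr$shape <- "dblexp"
    w <- purrr::pmap_dbl(tr, function(t0, A, tau_rise, tau_decay,
                                      shape = "dblexp", ...)
      kernel_width(A, tau_rise, tau_decay, shape))
    gap <- diff(tr$t0)
    if (any(gap < head(w, -1))) {
      abort("overlapping transients: onsets closer than one kernel width.")
    }
    transients <- tr
  }
  n <- round(duration * rate)
  time <- (seq_len(n) - 1) / rate
  s <- sum_kernels(time, transients)
  a <- sum_kernels(time, artifacts)
  g535 <- unname(artifact_gain["f535"] %||% artifact_gain[1])
  g480 <- unname(artifact_gain["f480"] %||% artifact_gain[2])
  bleach <- exp(-bleach_rate * time)
  rec <- with_seed(seed, {
    e1 <- rnorm(n, 0, noise_sd)
    e2 <- rnorm(n, 0, noise_sd)
    tibble(time_s = time,
           f480 = f480_base * bleach * (1 - s + g480 * a) * (1 + e2),
           f535 = f535_base * bleach * (1 + s + g535 * a) * (1 + e1))
  })
  truth <- if (is.null(transients) || nrow(transients) == 0) {
    transient_oracle_metrics(transient_spec(0))[0, ]
  } else {
    transient_oracle_metrics(transients)
  }
  list(recording = rec, truth = truth)
}
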