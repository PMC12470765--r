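#' Run a config-driven batch pipeline
#'
#' Executes a sequence of stages described in a YAML file (or an equivalent
#' list): `simulate_traces`, `analyze_traces`, `linearity`, `aggregates`,
#' `compare`. Each stage writes CSV/JSON outputs into its own subdirectory
#' of `out`, and a plain-text log records the package version, seed and
#' parameters, so a rerun with the same config and seed reproduces the
#' outputs byte for byte.
#'
#' Stage parameters (all optional unless noted):
#' \describe{
#'   \item{simulate_traces}{`n_recordings`, `duration`, `rate`, `noise_sd`,
#'     `transients` (list with `t0` vector and optional `A`, `tau_rise`,
#'     `tau_decay`). Writes `trace_<i>.csv` and `truth_<i>.csv`.}
#'   \item{analyze_traces}{`input` (directory of `trace_*.csv`; defaults to
#'     the simulate_traces output), config overrides (`k`,
#'     `mirror_threshold`, ...). Writes `peaks.csv` and `summary.json`.}
#'   \item{linearity}{`mask` (TIFF path) or `simulate` (params for
#'     [generate_mito_mask()]), `n_lines`. Writes `lines.csv`,
#'     `summary.json`.}
#'   \item{aggregates}{`images` (TIFF paths) or `simulate`
#'     (`n_images` + params for [generate_aggregate_image()]);
#'     `worm_threshold`, `threshold` (required, one value for the whole
#'     batch -- per-image thresholds are refused unless
#'     `allow_per_image: true`), `min_size`. Writes `rois.csv`,
#'     `fractions.json`.}
#'   \item{compare}{`input` (CSV path), `value`, `group` column names.
#'     Writes `comparison.json`.}
#' }
#'
#' @param config Path to a YAML config file, or a list with elements
#'   `stages` (list of stage descriptions) and optionally `out`, `seed`.
#' @param out Output directory (overrides the config).
#' @param seed Integer seed (overrides the config; default 1).
#' @return Invisibly, a named list of per-stage results.
#' @export
run_pipeline <- function(config, out = NULL, seed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste("config file not found:", config))
    config <- yaml::read_yaml(config)
  }
  out <- out %||% config$out
  if (is.null(out)) abort("no output directory: give `out` or set it in the config.")
  seed <- as.integer(seed %||% config$seed %||% 1L)
  stages <- config$stages
  if (is.null(stages) || !length(stages)) abort("config has no stages.")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  known <- c("simulate_traces", "analyze_traces", "linearity",
             "aggregates", "compare")
  results <- list()
  log_lines <- c(paste("wormquant", as.character(utils::packageVersion("wormquant"))),
                 paste("seed:", seed))
  for (st in stages) {
    name <- st$stage
    if (is.null(name) || !name %in% known) {
      abort(paste0("unknown stage '", name %||% "<missing>",
                   "'; known stages: ", paste(known, collapse = ", ")))
    }
    sdir <- file.path(out, name)
    dir.create(sdir, showWarnings = FALSE)
    results[[name]] <- switch(
      name,
      simulate_traces = stage_simulate_traces(st, sdir, seed),
      analyze_traces = stage_analyze_traces(st, sdir, out),
      linearity = stage_linearity(st, sdir, seed),
      aggregates = stage_aggregates(st, sdir, seed),
      compare = stage_compare(st, sdir))
    log_lines <- c(log_lines, paste0("stage ", name, ": ",
                                     yaml::as.yaml(st[setdiff(names(st), "stage")])))
  }
  writeLines(log_lines, file.path(out, "pipeline.log"))
  invisible(results)
}

stage_simulate_traces <- function(st, sdir, seed) {
  n_rec <- st$n_recordings %||% 1L
  tr <- if (!is.null(st$transients)) {
    do.call(transient_spec, st$transients)
  } else {
    transient_spec(t0 = seq(60, (st$duration %||% 900) - 120, by = 120))
  }
  files <- character(n_rec)
  for (i in seq_len(n_rec)) {
    sim <- simulate_fret_recording(
      tr, duration = st$duration %||% 900, rate = st$rate %||% 2.5,
      noise_sd = st$noise_sd %||% 0.01,
      bleach_rate = st$bleach_rate %||% 0, seed = seed + i)
    files[i] <- file.path(sdir, sprintf("trace_%03d.csv", i))
    write_recording_csv(sim$recording, files[i])
    write.csv(sim$truth, file.path(sdir, sprintf("truth_%03d.csv", i)),
              row.names = FALSE)
  }
  files
}

stage_analyze_traces <- function(st, sdir, out) {
  input <- st$input %||% file.path(out, "simulate_traces")
  if (!dir.exists(input) && !file.exists(input)) {
    abort(paste("analyze_traces input not found:", input))
  }
  files <- if (dir.exists(input)) {
    list.files(input, pattern = "^trace_.*\\.csv$", full.names = TRUE)
  } else input
  if (!length(files)) abort(paste("no trace_*.csv files in", input))
  cfg <- analysis_config(
    k = st$k %||% 4, mirror_threshold = st$mirror_threshold %||% -0.5,
    eps = st$eps %||% 0.1,
    baseline_window_s = st$baseline_window_s %||% 60)
  peaks <- purrr::map(files, function(f) {
    fit <- analyze_recording(read_recording_csv(f), cfg)
    pk <- fit$peaks
    if (nrow(pk)) pk$recording_id <- basename(f)
    pk
  })
  peaks <- dplyr::bind_rows(peaks)
  write.csv(peaks, file.path(sdir, "peaks.csv"), row.names = FALSE)
  write_json_summary(summarize_peaks(peaks), file.path(sdir, "summary.json"))
  peaks
}

stage_linearity <- function(st, sdir, seed) {
  if (!is.null(st$mask)) {
    if (!file.exists(st$mask)) abort(paste("mask file not found:", st$mask))
    mask <- read_mask_tiff(st$mask)
  } else {
    mask <- do.call(generate_mito_mask,
                    c(st$simulate %||% list(), list(seed = seed)))$mask
  }
  res <- assess_linearity(mask, n_lines = st$n_lines %||% 3, seed = seed)
  morph <- morphology_metrics(mask)
  write.csv(res$lines, file.path(sdir, "lines.csv"), row.names = FALSE)
  write_json_summary(c(as.list(glance(res)), as.list(glance(morph))),
                     file.path(sdir, "summary.json"))
  res
}

stage_aggregates <- function(st, sdir, seed) {
  thr <- st$threshold
  if (is.null(thr)) abort("aggregates stage needs a `threshold`.")
  if (length(thr) > 1 && !isTRUE(st$allow_per_image)) {
    abort(paste("per-image thresholds violate the consistent-threshold",
                "rule; set allow_per_image: true to override."))
  }
  imgs <- if (!is.null(st$images)) {
    missing <- st$images[!file.exists(unlist(st$images))]
    if (length(missing)) {
      abort(paste("image file not found:", paste(missing, collapse = ", ")))
    }
    purrr::map(st$images, read_image_tiff)
  } else {
    n_img <- st$simulate$n_images %||% 1L
    pars <- st$simulate[setdiff(names(st$simulate), "n_images")]
    purrr::map(seq_len(n_img), function(i)
      do.call(generate_aggregate_image, c(pars, list(seed = seed + i)))$image)
  }
  thr <- rep_len(thr, length(imgs))
  rows <- purrr::imap(imgs, function(img, i) {
    q <- quantify_aggregates(img, worm_threshold = st$worm_threshold %||% 35,
                             aggregate_threshold = thr[[i]],
                             min_size = st$min_size %||% 1)
    dplyr::bind_cols(tibble(image = i), glance(q))
  })
  tab <- dplyr::bind_rows(rows)
  write.csv(tab, file.path(sdir, "rois.csv"), row.names = FALSE)
  write_json_summary(list(n_images = length(imgs),
                          mean_fraction = mean(tab$fraction)),
                     file.path(sdir, "fractions.json"))
  tab
}

stage_compare <- function(st, sdir) {
  if (is.null(st$input) || !file.exists(st$input)) {
    abort(paste("compare input not found:", st$input %||% "<missing>"))
  }
  d <- read.csv(st$input)
  cmp <- compare_groups(d, !!rlang::sym(st$value %||% "value"),
                        !!rlang::sym(st$group %||% "group"))
  write_json_summary(list(glance = as.list(glance(cmp)),
                          groups = cmp$groups, pairwise = cmp$pairwise),
                     file.path(sdir, "comparison.json"))
  cmp
}
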