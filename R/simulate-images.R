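#' Generate a synthetic sarcomere-patterned mitochondrial mask
#'
#' Emulates the body-wall muscle phenotype: parallel rows of moderately
#' elongated mitochondrial units aligned with the longitudinal (row) axis.
#' Each unit is an axis-aligned `unit_length x unit_width` rectangle placed
#' on a regular within-row lattice of period `unit_length + inter_unit_gap`;
#' disorganization is injected by deleting each unit independently with
#' probability `gap_prob` and displacing it transversely by a rounded
#' `N(0, jitter_sd)` offset. Deletion draws happen before jitter draws, so
#' for a fixed seed the set of deleted units grows monotonically with
#' `gap_prob`.
#'
#' The expected fraction of an axis-parallel line covered by mitochondria is
#' `(1 - gap_prob) * unit_length / (unit_length + inter_unit_gap)`.
#'
#' @param n_rows Number of sarcomere rows.
#' @param unit_length,unit_width Unit size in pixels (length runs along the
#'   longitudinal axis).
#' @param inter_unit_gap Gap between consecutive units in a row (px, >= 0).
#' @param gap_prob Probability a unit is deleted, in `[0, 1]`.
#' @param jitter_sd SD of the transverse displacement (px).
#' @param image_shape `(rows, cols)` of the mask; the width must be at
#'   least 200 px so that profile lines fit. By default the sarcomere rows
#'   tile the full image height (`n_rows * unit_width` rows), so with no
#'   deletions, no gaps and no jitter every row-aligned line is fully
#'   covered.
#' @param seed Integer seed.
#' @return List with `mask` (binary matrix), `expected_coverage`
#'   (fraction), `n_units_kept`, and `row_tops` (first pixel row of each
#'   sarcomere band before jitter).
#' @export
generate_mito_mask <- function(n_rows = 8, unit_length = 20, unit_width = 4,
                               inter_unit_gap = 0, gap_prob = 0,
                               jitter_sd = 0,
                               image_shape = c(n_rows * unit_width, 260),
                               seed = 1) {
  if (gap_prob < 0 || gap_prob > 1) abort("`gap_prob` must lie in [0, 1].")
  if (inter_unit_gap < 0) abort("`inter_unit_gap` must be >= 0.")
  if (image_shape[2] < 200) {
    abort("mask width must be >= 200 px (the profile line length).")
  }
  if (image_shape[2] < unit_length || image_shape[1] < unit_width) {
    abort("image too small to hold a single unit.")
  }
  nr <- image_shape[1]; nc <- image_shape[2]
  period <- unit_length + inter_unit_gap
  n_units_row <- ceiling(nc / period)
  row_pitch <- nr / n_rows
  row_tops <- round(row_pitch * (seq_len(n_rows) - 1)) + 1L
  with_seed(seed, {
    n_total <- n_rows * n_units_row
    # deletions are drawn before jitter so that, for a fixed seed, the
    # deleted set grows monotonically with gap_prob
    deleted <- runif(n_total) < gap_prob
    jitter <- if (jitter_sd > 0) round(rnorm(n_total, 0, jitter_sd))
              else integer(n_total)
    mask <- matrix(0L, nr, nc)
    kept <- 0L
    u <- 0L
    for (k in seq_len(n_rows)) {
      for (j in seq_len(n_units_row)) {
        u <- u + 1L
        if (deleted[u]) next
        kept <- kept + 1L
        c0 <- (j - 1L) * period + 1L
        c1 <- min(c0 + unit_length - 1L, nc)
        r0 <- row_tops[k] + jitter[u]
        r1 <- min(nr, r0 + unit_width - 1L)
        r0 <- max(1L, r0)
        if (r0 <= r1) mask[r0:r1, c0:c1] <- 1L
      }
    }
    list(mask = mask,
         expected_coverage = (1 - gap_prob) * unit_length / period,
         n_units_kept = kept, row_tops = row_tops)
  })
}

#' Generate a synthetic Thioflavin-T worm image with known aggregate truth
#'
#' Paints an elliptical worm body on a dark background and drops bright
#' circular aggregates fully inside the body, then adds Gaussian noise.
#' Ground truth is computed by direct pixel counting on the noise-free
#' label image: the aggregate area fraction is the number of painted
#' aggregate pixels over the number of painted worm pixels.
#'
#' @param n_aggregates Number of aggregates.
#' @param radii Aggregate radii in px (recycled to `n_aggregates`).
#' @param centers Optional matrix/tibble of aggregate centers
#'   `(row, col)`; when supplied, any aggregate whose disk leaves the worm
#'   body is an error. When `NULL`, centers are drawn uniformly among
#'   positions keeping the whole disk inside the worm.
#' @param worm_center,worm_semiaxes Ellipse descriptor of the worm body
#'   (row/col center and semi-axes in px); defaults fill ~half the frame.
#' @param intensity_aggregate,intensity_body,intensity_background Mean
#'   intensities (a.u.); must satisfy aggregate > body > background.
#' @param noise_sd Gaussian noise SD (a.u.).
#' @param image_shape `(rows, cols)` in px.
#' @param seed Integer seed.
#' @return List with `image` (numeric matrix), `labels` (0 background,
#'   1 worm body, 2 aggregate), and `truth` (class `aggregate_quant`:
#'   per-aggregate painted areas, `total_aggregate_area`, `worm_area`,
#'   `fraction`).
#' @export
generate_aggregate_image <- function(n_aggregates = 5, radii = 5,
                                     centers = NULL,
                                     worm_center = image_shape / 2,
                                     worm_semiaxes = image_shape * 0.35,
                                     intensity_aggregate = 200,
                                     intensity_body = 60,
                                     intensity_background = 10,
                                     noise_sd = 2,
                                     image_shape = c(192, 192), seed = 1) {
  if (!(intensity_aggregate > intensity_body &&
        intensity_body > intensity_background)) {
    abort("intensities must satisfy aggregate > body > background.")
  }
  if (n_aggregates < 0) abort("`n_aggregates` must be >= 0.")
  nr <- image_shape[1]; nc <- image_shape[2]
  radii <- rep_len(radii, max(n_aggregates, 1))
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  worm <- ((rr - worm_center[1]) / worm_semiaxes[1])^2 +
    ((cc - worm_center[2]) / worm_semiaxes[2])^2 <= 1
  if (!any(worm)) abort("worm ellipse covers no pixels.")
  disk_ok <- function(r0, c0, rad) {
    # every pixel of the rasterized disk must be a worm pixel
    win_r <- max(1, floor(r0 - rad)):min(nr, ceiling(r0 + rad))
    win_c <- max(1, floor(c0 - rad)):min(nc, ceiling(c0 + rad))
    sel <- outer(win_r - r0, win_c - c0, function(a, b) a^2 + b^2) <= rad^2
    all(worm[win_r, win_c][sel]) &&
      (r0 - rad >= 1 && r0 + rad <= nr && c0 - rad >= 1 && c0 + rad <= nc)
  }
  with_seed(seed, {
    agg <- matrix(FALSE, nr, nc)
    areas <- integer(0)
    if (n_aggregates > 0) {
      if (!is.null(centers)) {
        centers <- as.matrix(centers)
        if (nrow(centers) != n_aggregates) {
          abort("`centers` must have one row per aggregate.")
        }
      }
      for (i in seq_len(n_aggregates)) {
        rad <- radii[i]
        if (!is.null(centers)) {
          r0 <- centers[i, 1]; c0 <- centers[i, 2]
          if (!disk_ok(r0, c0, rad)) {
            abort("aggregate placed outside the worm body.")
          }
        } else {
          placed <- FALSE
          for (try in 1:500) {
            r0 <- runif(1, 1 + rad, nr - rad)
            c0 <- runif(1, 1 + rad, nc - rad)
            if (disk_ok(r0, c0, rad)) { placed <- TRUE; break }
          }
          if (!placed) abort("could not place an aggregate inside the worm.")
        }
        disk <- (rr - r0)^2 + (cc - c0)^2 <= rad^2
        areas <- c(areas, sum(disk & !agg))
        agg <- agg | disk
      }
    }
    labels <- matrix(0L, nr, nc)
    labels[worm] <- 1L
    labels[agg] <- 2L
    img <- matrix(intensity_background, nr, nc)
    img[worm] <- intensity_body
    img[agg] <- intensity_aggregate
    if (noise_sd > 0) img <- img + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
    truth <- new_aggregate_quant(
      rois = tibble(roi = seq_along(areas), area = areas),
      worm_area = sum(worm))
    list(image = img, labels = labels, truth = truth)
  })
}
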