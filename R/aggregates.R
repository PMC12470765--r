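new_aggregate_quant <- function(rois, worm_area) {
  total <- sum(rois$area)
  if (worm_area <= 0) abort("worm area must be positive.")
  structure(list(rois = rois, total_aggregate_area = total,
                 worm_area = worm_area, fraction = total / worm_area),
            class = "aggregate_quant")
}

#' @export
print.aggregate_quant <- function(x, ...) {
  cat("<aggregate_quant>", nrow(x$rois), "ROI(s), total",
      x$total_aggregate_area, "px over worm", x$worm_area, "px: fraction",
      sprintf("%.4f", x$fraction), "\n")
  invisible(x)
}

#' Maximum-intensity projection of an image stack
#'
#' Z-stacks are reduced to a single plane by maximum-intensity projection
#' before thresholding; 2-D input passes through unchanged.
#'
#' @param x Numeric matrix or 3-D array (rows x cols x planes).
#' @return Numeric matrix.
#' @export
project_stack <- function(x) {
  if (is.matrix(x)) return(x)
  if (length(dim(x)) != 3) abort("expected a matrix or a 3-D array.")
  apply(x, c(1, 2), max)
}

#' Segment the worm body from a fluorescence image
#'
#' Thresholds the (projected) image, keeps the largest 8-connected
#' component and fills its internal holes, yielding the worm-body mask
#' whose pixel count normalizes the aggregate area.
#'
#' @param image Numeric matrix or 3-D stack.
#' @param threshold Intensity threshold separating worm from background.
#' @return Binary matrix (integer 0/1) of the worm body.
#' @export
segment_worm <- function(image, threshold) {
  image <- project_stack(image)
  fg <- matrix(as.integer(image > threshold), nrow(image), ncol(image))
  if (!any(fg == 1L)) abort("no worm found: no pixel above the threshold.")
  lab <- label_components(fg)
  areas <- tabulate(lab[lab > 0])
  keep <- which.max(areas)
  worm <- matrix(as.numeric(lab == keep), nrow(image), ncol(image))
  worm <- EBImage::imageData(EBImage::fillHull(worm))
  matrix(as.integer(worm != 0), nrow(image), ncol(image))
}

#' Detect aggregate ROIs inside the worm body
#'
#' Connected components (8-connectivity) of supra-threshold pixels inside
#' the worm mask, filtered by a minimum size. The threshold is meant to be
#' held constant across all images of a batch (the consistency rule);
#' a threshold at or below the background median triggers an
#' over-detection warning.
#'
#' @param image Numeric matrix or 3-D stack.
#' @param worm_mask Binary worm-body mask from [segment_worm()].
#' @param threshold Aggregate intensity threshold (held fixed per batch).
#' @param min_size Minimum ROI area in pixels (>= 1).
#' @return Tibble with one row per ROI: `roi`, `area`, `centroid_row`,
#'   `centroid_col`.
#' @export
detect_aggregates <- function(image, worm_mask, threshold, min_size = 1) {
  image <- project_stack(image)
  assert_binary_mask(worm_mask)
  if (min_size < 1) abort("`min_size` must be >= 1 pixel.")
  bg <- image[worm_mask == 0]
  if (length(bg) && threshold <= median(bg)) {
    warn("threshold is at or below the background median; expect over-detection.")
  }
  fg <- matrix(as.integer(image > threshold), nrow(image), ncol(image))
  fg <- fg * worm_mask
  lab <- label_components(fg)
  if (max(lab) == 0) {
    return(tibble(roi = integer(), area = integer(),
                  centroid_row = numeric(), centroid_col = numeric()))
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  d <- tibble(l = lab[lab > 0], r = idx[, 1], c = idx[, 2])
  out <- dplyr::summarise(dplyr::group_by(d, .data$l),
                          area = dplyr::n(),
                          centroid_row = mean(.data$r),
                          centroid_col = mean(.data$c), .groups = "drop")
  out <- out[out$area >= min_size, , drop = FALSE]
  tibble(roi = seq_len(nrow(out)), area = as.integer(out$area),
         centroid_row = out$centroid_row, centroid_col = out$centroid_col)
}

#' Aggregate area fraction of a worm
#'
#' The sum of all ROI areas normalized to the worm-body area: the fraction
#' of the worm occupied by Thioflavin-T-positive aggregates.
#'
#' @param rois ROI tibble from [detect_aggregates()].
#' @param worm_mask Binary worm-body mask.
#' @return An `aggregate_quant` object (`rois`, `total_aggregate_area`,
#'   `worm_area`, `fraction`).
#' @export
aggregate_fraction <- function(rois, worm_mask) {
  assert_binary_mask(worm_mask)
  worm_area <- sum(worm_mask)
  if (worm_area == 0) abort("worm area is zero.")
  new_aggregate_quant(rois, worm_area)
}

#' Quantify aggregates in one image, end to end
#'
#' Convenience composition: maximum-intensity projection (for stacks),
#' worm segmentation, ROI detection and area-fraction computation.
#'
#' @inheritParams detect_aggregates
#' @param worm_threshold Threshold for the worm-body segmentation.
#' @param aggregate_threshold Threshold for aggregate detection (fixed per
#'   batch).
#' @return An `aggregate_quant` object.
#' @export
#' @examples
#' gen <- generate_aggregate_image(n_aggregates = 3, seed = 1)
#' quantify_aggregates(gen$image, worm_threshold = 35,
#'                     aggregate_threshold = 130)$fraction
quantify_aggregates <- function(image, worm_threshold, aggregate_threshold,
                                min_size = 1) {
  image <- project_stack(image)
  worm <- segment_worm(image, worm_threshold)
  rois <- detect_aggregates(image, worm, aggregate_threshold, min_size)
  aggregate_fraction(rois, worm)
}
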