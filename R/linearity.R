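#' Threshold a grayscale image into a binary mitochondrial mask
#'
#' Fallback segmentation when a pre-segmented mask is not supplied:
#' `method = "fixed"` keeps pixels strictly above `threshold`;
#' `method = "otsu"` picks the threshold by Otsu's criterion
#' (via [EBImage::otsu()] on the intensity range of the image).
#' An already-binary image passes through unchanged.
#'
#' @param image Numeric matrix (grayscale).
#' @param method `"fixed"` or `"otsu"`.
#' @param threshold Threshold value for `method = "fixed"`.
#' @return Integer matrix of 0/1, same shape as `image`.
#' @export
binarize_image <- function(image, method = c("fixed", "otsu"),
                           threshold = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(image))
  if (method == "fixed") {
    if (is.null(threshold)) abort("`threshold` required for method 'fixed'.")
    thr <- threshold
  } else {
    rng <- range(image)
    if (diff(rng) == 0) {
      abort("constant image: automatic threshold is undefined.")
    }
    sc <- (image - rng[1]) / diff(rng)
    thr <- rng[1] + diff(rng) * EBImage::otsu(EBImage::Image(sc))
  }
  out <- matrix(as.integer(image > thr), nrow(image), ncol(image))
  out
}

#' Extract a 200-sample binary line profile from a mask
#'
#' Samples the mask at unit-pixel spacing along a straight line using
#' nearest-pixel reads, then applies the published binarization rule:
#' intensity zero maps to 0, any non-zero intensity to 1.
#'
#' @param mask Binary matrix (rows x cols; the longitudinal axis runs along
#'   matrix rows, i.e. the column direction).
#' @param anchor Numeric length-2 `(row, col)` of the first sample point.
#' @param direction Numeric length-2 unit vector `(drow, dcol)`.
#' @param n Number of samples (default 200).
#' @return Integer vector of `n` binary values.
#' @export
sample_line_profile <- function(mask, anchor, direction, n = 200) {
  assert_binary_mask(mask)
  direction <- direction / sqrt(sum(direction^2))
  steps <- seq_len(n) - 1
  rr <- round(anchor[1] + steps * direction[1])
  cc <- round(anchor[2] + steps * direction[2])
  if (any(rr < 1 | rr > nrow(mask) | cc < 1 | cc > ncol(mask))) {
    abort("line exits the image bounds.")
  }
  as.integer(mask[cbind(rr, cc)] != 0)
}

#' Linearity score of one line profile
#'
#' The sum of the 200 binary samples: 200 means uninterrupted mitochondrial
#' presence along the whole line, 0 an empty line, intermediate values
#' increasing discontinuity.
#'
#' @param profile Integer vector of exactly 200 values in `{0, 1}`.
#' @return Integer score in `[0, 200]`.
#' @export
linearity_score <- function(profile) {
  if (length(profile) != 200) {
    abort("a line profile must have exactly 200 samples.")
  }
  if (!all(profile %in% c(0, 1))) abort("profile values must be 0 or 1.")
  as.integer(sum(profile))
}

#' Place random 200-pixel profile lines over a mask
#'
#' By default lines run parallel to the declared longitudinal axis (matrix
#' rows) at uniformly random transverse offsets and random in-bounds start
#' positions; `orientation = "random"` instead draws a uniformly random
#' angle and a start position keeping all 200 samples inside the image.
#'
#' @param mask Binary matrix.
#' @param n_lines Number of lines (default 3, as in the published
#'   procedure).
#' @param orientation `"axis"` (default) or `"random"`.
#' @param n Samples per line (default 200).
#' @param seed Optional integer seed for reproducible placements.
#' @return Tibble with one row per line: `row0`, `col0`, `drow`, `dcol`.
#' @export
place_profile_lines <- function(mask, n_lines = 3,
                                orientation = c("axis", "random"),
                                n = 200, seed = NULL) {
  assert_binary_mask(mask)
  orientation <- match.arg(orientation)
  if (orientation == "axis" && ncol(mask) < n) {
    abort("mask narrower than the line length along the longitudinal axis.")
  }
  with_seed(seed, {
    rows <- purrr::map(seq_len(n_lines), function(i) {
      if (orientation == "axis") {
        tibble(row0 = sample.int(nrow(mask), 1),
               col0 = sample.int(ncol(mask) - n + 1, 1),
               drow = 0, dcol = 1)
      } else {
        for (try in 1:200) {
          th <- runif(1, 0, 2 * pi)
          d <- c(sin(th), cos(th))
          r0 <- runif(1, 1, nrow(mask))
          c0 <- runif(1, 1, ncol(mask))
          r1 <- r0 + (n - 1) * d[1]; c1 <- c0 + (n - 1) * d[2]
          if (r1 >= 1 && r1 <= nrow(mask) && c1 >= 1 && c1 <= ncol(mask)) {
            return(tibble(row0 = r0, col0 = c0, drow = d[1], dcol = d[2]))
          }
        }
        abort("mask too small to place a line at a random orientation.")
      }
    })
    dplyr::bind_rows(rows)
  })
}

#' Assess mitochondrial linearity of a mask
#'
#' Draws `n_lines` random 200-pixel lines (see [place_profile_lines()]),
#' scores each (see [linearity_score()]), and reports the mean score and
#' the percentage of line covered by mitochondria
#' (`100 * mean score / 200`).
#'
#' @inheritParams place_profile_lines
#' @return A list of class `linearity_result`: `lines` (tibble with
#'   placements and per-line `score`), `mean_score`, `percent_coverage`.
#' @export
#' @examples
#' gen <- generate_mito_mask(seed = 1)
#' assess_linearity(gen$mask, seed = 1)$percent_coverage
assess_linearity <- function(mask, n_lines = 3,
                             orientation = c("axis", "random"),
                             n = 200, seed = NULL) {
  orientation <- match.arg(orientation)
  lines <- place_profile_lines(mask, n_lines, orientation, n, seed)
  lines$score <- purrr::pmap_int(lines, function(row0, col0, drow, dcol) {
    prof <- sample_line_profile(mask, c(row0, col0), c(drow, dcol), n)
    as.integer(sum(prof))
  })
  structure(list(lines = lines, mean_score = mean(lines$score),
                 percent_coverage = 100 * mean(lines$score) / n),
            class = "linearity_result")
}

#' @export
print.linearity_result <- function(x, ...) {
  cat("<linearity_result> scores:", paste(x$lines$score, collapse = ", "),
      "| mean", round(x$mean_score, 1),
      "| coverage", sprintf("%.1f%%", x$percent_coverage), "\n")
  invisible(x)
}

#' Morphology metrics of a mitochondrial mask
#'
#' Connected components (8-connectivity) give the mitochondrial unit count;
#' each unit's elongation is the major/minor axis ratio of its
#' moment-equivalent ellipse (second central moments with the 1/12 unit
#' pixel-extent term, so an axis-aligned L x W rectangle scores exactly
#' L / W); total area fraction is foreground pixels over all pixels. The
#' whole frame is treated as one cell unless a `cell_mask` restricts it.
#'
#' @param mask Binary matrix.
#' @param cell_mask Optional binary matrix delimiting the cell; components
#'   and areas are restricted to it.
#' @return A list of class `mito_morphology`: `n_units`,
#'   `total_area_fraction`, and `units` (tibble of per-component `area` and
#'   `aspect_ratio`).
#' @export
morphology_metrics <- function(mask, cell_mask = NULL) {
  assert_binary_mask(mask)
  if (!is.null(cell_mask)) {
    assert_binary_mask(cell_mask)
    stopifnot(dim(cell_mask) == dim(mask))
    mask <- mask * cell_mask
    denom <- sum(cell_mask)
  } else {
    denom <- length(mask)
  }
  lab <- label_components(mask)
  nlab <- max(lab)
  units <- if (nlab == 0) {
    tibble(unit = integer(), area = integer(), aspect_ratio = numeric())
  } else {
    rows <- purrr::map(seq_len(nlab), function(l) {
      idx <- which(lab == l, arr.ind = TRUE)
      r <- idx[, 1]; c <- idx[, 2]
      mu20 <- mean((r - mean(r))^2) + 1 / 12
      mu02 <- mean((c - mean(c))^2) + 1 / 12
      mu11 <- mean((r - mean(r)) * (c - mean(c)))
      common <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
      l1 <- (mu20 + mu02) / 2 + common
      l2 <- (mu20 + mu02) / 2 - common
      tibble(unit = l, area = nrow(idx), aspect_ratio = sqrt(l1 / l2))
    })
    dplyr::bind_rows(rows)
  }
  structure(list(n_units = nlab,
                 total_area_fraction = sum(mask != 0) / denom,
                 units = units),
            class = "mito_morphology")
}

#' @export
print.mito_morphology <- function(x, ...) {
  cat("<mito_morphology>", x$n_units, "unit(s), area fraction",
      sprintf("%.3f", x$total_area_fraction), "\n")
  if (x$n_units > 0) {
    cat("  mean aspect ratio", sprintf("%.2f", mean(x$units$aspect_ratio)),
        "\n")
  }
  invisible(x)
}
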