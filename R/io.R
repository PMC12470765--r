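#' Read and write dual-channel recordings as CSV
#'
#' Recordings are exchanged as plain CSV with the header
#' `time_s,f480,f535`.
#'
#' @param path File path.
#' @return `read_recording_csv()` returns the recording tibble.
#' @export
read_recording_csv <- function(path) {
  if (!file.exists(path)) abort(paste("recording file not found:", path))
  d <- as_tibble(read.csv(path))
  validate_recording(d)
  d[, c("time_s", "f480", "f535")]
}

#' @rdname read_recording_csv
#' @param rec Recording tibble (`time_s`, `f480`, `f535`).
#' @export
write_recording_csv <- function(rec, path) {
  validate_recording(rec)
  write.csv(rec, path, row.names = FALSE)
  invisible(path)
}

#' Read and write masks and grayscale images as single-page TIFF
#'
#' Intensities are stored scaled to `[0, 1]` by `max_value` (a.u. per TIFF
#' unit); masks use `max_value = 1`. Reading a mask re-binarizes at 0.5 to
#' be robust to bit-depth rounding.
#'
#' @param path File path.
#' @param max_value Full-scale intensity in a.u.
#' @return Numeric matrix (image) or integer 0/1 matrix (mask).
#' @export
read_image_tiff <- function(path, max_value = 255) {
  if (!file.exists(path)) abort(paste("image file not found:", path))
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  x * max_value
}

#' @rdname read_image_tiff
#' @param image Numeric matrix.
#' @export
write_image_tiff <- function(image, path, max_value = 255) {
  x <- pmin(pmax(image / max_value, 0), 1)
  tiff::writeTIFF(x, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname read_image_tiff
#' @export
read_mask_tiff <- function(path) {
  x <- read_image_tiff(path, max_value = 1)
  matrix(as.integer(x > 0.5), nrow(x), ncol(x))
}

#' @rdname read_image_tiff
#' @param mask Binary matrix.
#' @export
write_mask_tiff <- function(mask, path) {
  assert_binary_mask(mask)
  write_image_tiff(mask, path, max_value = 1)
}

write_json_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
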