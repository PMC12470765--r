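#' Plot a trace analysis: ratio, baseline and accepted peaks
#'
#' @param object A `ca_analysis` from [analyze_recording()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ca_analysis <- function(object, ...) {
  tr <- object$trace
  p <- ggplot2::ggplot(tr, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$ratio), linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$baseline), colour = "steelblue",
                       linetype = "dashed") +
    ggplot2::labs(x = "time (s)", y = "F535 / F480 ratio",
                  title = sprintf("%d accepted Ca peak(s)",
                                  nrow(object$peaks))) +
    ggplot2::theme_minimal()
  if (nrow(object$peaks)) {
    p <- p + ggplot2::geom_point(
      data = object$peaks,
      ggplot2::aes(x = .data$t_apex,
                   y = .data$baseline_ratio * (1 + .data$height_pct / 100)),
      colour = "firebrick", shape = 17)
  }
  p
}

#' Plot a binary mask, optionally with profile lines
#'
#' @param mask Binary matrix.
#' @param lines Optional tibble of line placements (from
#'   [place_profile_lines()] or a `linearity_result$lines`).
#' @param n Samples per line (for drawing the segment, default 200).
#' @return A ggplot object.
#' @export
plot_mask <- function(mask, lines = NULL, n = 200) {
  assert_binary_mask(mask)
  d <- tibble(row = rep(seq_len(nrow(mask)), times = ncol(mask)),
              col = rep(seq_len(ncol(mask)), each = nrow(mask)),
              value = as.vector(mask))
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row,
                                       fill = factor(.data$value))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`0` = "grey15", `1` = "grey90"),
                               guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "col (px)", y = "row (px)") +
    ggplot2::theme_minimal()
  if (!is.null(lines)) {
    seg <- dplyr::mutate(lines,
                         row1 = .data$row0 + (n - 1) * .data$drow,
                         col1 = .data$col0 + (n - 1) * .data$dcol)
    p <- p + ggplot2::geom_segment(
      data = seg, inherit.aes = FALSE, colour = "orange",
      ggplot2::aes(x = .data$col0, y = .data$row0,
                   xend = .data$col1, yend = .data$row1))
  }
  p
}

#' Plot group means with SEM error bars and significance annotation
#'
#' @param object A `group_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.group_comparison <- function(object, ...) {
  g <- object$groups
  ggplot2::ggplot(g, ggplot2::aes(.data$group, .data$mean)) +
    ggplot2::geom_col(fill = "grey70", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.15) +
    ggplot2::labs(y = paste(object$metric, "(mean ± SEM)"), x = NULL,
                  title = paste0(object$metric, ": p = ",
                                 format.pval(object$omnibus_p, digits = 2),
                                 " ", object$stars)) +
    ggplot2::theme_minimal()
}
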