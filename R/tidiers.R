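# broom-style tidiers: tidy() gives the per-unit table, glance() the
# one-row model/result summary.

#' @exportS3Method generics::tidy
tidy.ca_analysis <- function(x, ...) x$peaks

#' @exportS3Method generics::glance
glance.ca_analysis <- function(x, ...) {
  dplyr::bind_cols(x$summary,
                   tibble(n_candidates = nrow(x$candidates),
                          n_edge_discarded = x$n_edge_discarded,
                          sigma = x$sigma))
}

#' @exportS3Method generics::tidy
tidy.linearity_result <- function(x, ...) x$lines

#' @exportS3Method generics::glance
glance.linearity_result <- function(x, ...) {
  tibble(n_lines = nrow(x$lines), mean_score = x$mean_score,
         percent_coverage = x$percent_coverage)
}

#' @exportS3Method generics::tidy
tidy.mito_morphology <- function(x, ...) x$units

#' @exportS3Method generics::glance
glance.mito_morphology <- function(x, ...) {
  tibble(n_units = x$n_units,
         total_area_fraction = x$total_area_fraction,
         mean_aspect_ratio = if (x$n_units) mean(x$units$aspect_ratio)
                             else NA_real_)
}

#' @exportS3Method generics::tidy
tidy.aggregate_quant <- function(x, ...) x$rois

#' @exportS3Method generics::glance
glance.aggregate_quant <- function(x, ...) {
  tibble(n_rois = nrow(x$rois),
         total_aggregate_area = x$total_aggregate_area,
         worm_area = x$worm_area, fraction = x$fraction)
}

#' @exportS3Method generics::tidy
tidy.group_comparison <- function(x, ...) x$pairwise

#' @exportS3Method generics::glance
glance.group_comparison <- function(x, ...) {
  tibble(metric = x$metric, test = x$test, n_groups = nrow(x$groups),
         omnibus_p = x$omnibus_p, stars = x$stars,
         sensitivity_p = if (is.null(x$sensitivity)) NA_real_
                         else x$sensitivity$p[1])
}
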