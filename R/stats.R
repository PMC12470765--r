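#' Compare a metric between experimental groups
#'
#' Implements the study-style statistical protocol: each group is first
#' checked for normality (Lilliefors-corrected Kolmogorov-Smirnov test,
#' since the normal parameters are estimated from the data); two groups
#' are compared with a two-tailed unpaired Student's t-test, three or more
#' with a one-way ANOVA followed by Tukey's HSD post hoc pairwise
#' comparisons. Significance stars follow the conventional thresholds
#' (* p < 0.05, ** p < 0.01, *** p < 0.001, **** p < 0.0001). When any
#' group fails the normality check, the parametric result is still
#' reported, together with a labelled rank-based sensitivity test
#' (Wilcoxon rank-sum for two groups, Kruskal-Wallis otherwise).
#'
#' @param data A data frame with one row per observation.
#' @param value Column holding the metric (tidy-eval).
#' @param group Column holding the group label (tidy-eval).
#' @param metric Optional metric name carried into the output.
#' @return An object of class `group_comparison`: `groups` (per-group `n`,
#'   `mean`, `sem`, normality p-value and flag), `test` (`"t"` or
#'   `"anova"`), `omnibus_p`, `stars`, `pairwise` (Tukey rows when >= 3
#'   groups), `sensitivity` (rank-based test, when run).
#' @export
#' @examples
#' d <- data.frame(v = c(rnorm(20), rnorm(20, 2)),
#'                 g = rep(c("ctrl", "rnai"), each = 20))
#' compare_groups(d, v, g)
compare_groups <- function(data, value, group, metric = NULL) {
  v <- rlang::eval_tidy(enquo(value), data)
  g <- rlang::eval_tidy(enquo(group), data)
  metric <- metric %||% as_name(enquo(value))
  ok <- !is.na(v) & !is.na(g)
  v <- v[ok]; g <- as.character(g[ok])
  labs <- unique(g)
  if (length(labs) < 2) abort("need at least 2 groups.")
  ns <- table(g)
  if (any(ns < 2)) {
    abort(paste("every group needs n >= 2; offending:",
                paste(names(ns)[ns < 2], collapse = ", ")))
  }
  per <- purrr::map(labs, function(l) {
    x <- v[g == l]
    np <- tryCatch(nortest::lillie.test(x)$p.value,
                   error = function(e) NA_real_)
    tibble(group = l, n = length(x), mean = mean(x), sem = sem(x),
           normality_p = np,
           normal = is.na(np) | np >= 0.05)
  })
  groups <- dplyr::bind_rows(per)
  any_nonnormal <- any(!groups$normal)
  sensitivity <- NULL
  if (length(labs) == 2) {
    test <- "t"
    ht <- t.test(v[g == labs[1]], v[g == labs[2]], var.equal = TRUE,
                 alternative = "two.sided")
    omnibus_p <- ht$p.value
    pairwise <- tibble(group1 = labs[1], group2 = labs[2],
                       diff = ht$estimate[1] - ht$estimate[2],
                       p_adj = omnibus_p, stars = p_stars(omnibus_p))
    if (any_nonnormal) {
      wp <- wilcox.test(v[g == labs[1]], v[g == labs[2]], exact = FALSE)
      sensitivity <- tibble(test = "wilcoxon rank-sum", p = wp$p.value,
                            stars = p_stars(wp$p.value))
    }
  } else {
    test <- "anova"
    gf <- factor(g)
    fit <- aov(v ~ gf)
    omnibus_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- TukeyHSD(fit)$gf
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    pairwise <- tibble(group1 = vapply(pairs, `[`, "", 1),
                       group2 = vapply(pairs, `[`, "", 2),
                       diff = tk[, "diff"], p_adj = tk[, "p adj"],
                       stars = p_stars(tk[, "p adj"]))
    if (any_nonnormal) {
      kw <- stats::kruskal.test(v, gf)
      sensitivity <- tibble(test = "kruskal-wallis", p = kw$p.value,
                            stars = p_stars(kw$p.value))
    }
  }
  structure(list(metric = metric, groups = groups, test = test,
                 omnibus_p = omnibus_p, stars = p_stars(omnibus_p),
                 pairwise = pairwise, sensitivity = sensitivity),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> metric:", x$metric, "| test:",
      if (x$test == "t") "two-tailed unpaired t-test"
      else "one-way ANOVA + Tukey HSD",
      "| p =", format.pval(x$omnibus_p, digits = 3), x$stars, "\n")
  print(x$groups)
  if (x$test == "anova") {
    cat("pairwise (Tukey):\n")
    print(x$pairwise)
  }
  if (!is.null(x$sensitivity)) {
    cat("normality failed in >= 1 group; rank-based sensitivity test:\n")
    print(x$sensitivity)
  }
  invisible(x)
}
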