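#' Significance stars from a p-value
#'
#' The conventional ladder: `***` for p < 0.001, `**` for p < 0.01, `*` for
#' p < 0.05, `ns` otherwise.
#'
#' @param p p-value in `[0, 1]`.
#' @return one of `"ns"`, `"*"`, `"**"`, `"***"`.
#' @export
p_stars <- function(p) {
  stopifnot(is.numeric(p), p >= 0, p <= 1)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Two-group one-way ANOVA comparison
#'
#' Classic equal-variance one-way ANOVA between two groups. For two groups
#' the F statistic equals the square of the pooled-variance t statistic, and
#' the p-values coincide.
#'
#' @param values_a,values_b numeric vectors, each with at least 2 values.
#' @param quantity_name label for the quantity compared.
#' @return object of class `group_comparison`: list with `quantity_name`,
#'   `mean_a`, `sd_a`, `n_a`, `mean_b`, `sd_b`, `n_b`, `f_statistic`,
#'   `p_value`, `stars`.
#' @export
anova_compare <- function(values_a, values_b, quantity_name = "quantity") {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs at least 2 values")
  y <- c(values_a, values_b)
  if (stats::var(y) == 0)
    stop("total variance is zero; groups are degenerate")
  g <- factor(rep(c("a", "b"), c(length(values_a), length(values_b))))
  fit <- stats::oneway.test(y ~ g, var.equal = TRUE)
  # identical groups: between-group variance 0 => F = 0, p = 1
  f <- unname(fit$statistic)
  p <- unname(fit$p.value)
  if (!is.finite(f)) { f <- 0; p <- 1 }
  structure(list(quantity_name = quantity_name,
                 mean_a = mean(values_a), sd_a = stats::sd(values_a),
                 n_a = length(values_a),
                 mean_b = mean(values_b), sd_b = stats::sd(values_b),
                 n_b = length(values_b),
                 f_statistic = f, p_value = p, stars = p_stars(p)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %.4g +/- %.3g vs %.4g +/- %.3g, F = %.3g, p = %.3g %s\n",
              x$quantity_name, x$mean_a, x$sd_a, x$mean_b, x$sd_b,
              x$f_statistic, x$p_value, x$stars))
  invisible(x)
}

#' Feature-wise and S/N-wise group comparison report
#'
#' Compares every pair of groups feature by feature (contrast, entropy,
#' energy, homogeneity — in that order) with one-way ANOVA on the per-patch
#' values, and additionally compares the combined Taguchi S/N score computed
#' per image (or per patch when no `source_image` column is present). The
#' first group of each pair acts as the benchmark. Raw p-values are reported
#' with significance stars and no multiple-testing correction.
#'
#' @param features patch-level feature table with a `group` column (and
#'   optionally `source_image`), e.g. row-bound [patch_features()] outputs.
#' @param directions,combiner passed to the S/N scoring; see
#'   [combined_snr()].
#' @return data.frame of class `group_report`, one row per (quantity,
#'   group-pair): columns `group_a`, `group_b`, `quantity`, `mean_a`, `sd_a`,
#'   `mean_b`, `sd_b`, `f_statistic`, `p_value`, `stars`.
#' @export
summarize_groups <- function(features, directions = default_directions(),
                             combiner = c("pooled", "per_feature")) {
  combiner <- match.arg(combiner)
  if (!"group" %in% names(features))
    stop("`features` must have a `group` column")
  groups <- unique(features$group)
  if (length(groups) < 2L) stop("need at least 2 groups to compare")
  feat_order <- c("contrast", "entropy", "energy", "homogeneity")
  per_unit_snr <- function(sub) {
    if ("source_image" %in% names(features) &&
        !anyNA(sub$source_image) &&
        length(unique(sub$source_image)) >= 2L) {
      per_image_snr(sub, directions, combiner)$snr_combined
    } else {
      vapply(seq_len(nrow(sub)), function(k) {
        combined_snr(sub[k, , drop = FALSE], directions,
                     combiner)$snr_combined
      }, numeric(1))
    }
  }
  rows <- list()
  for (i in seq_len(length(groups) - 1L)) {
    for (j in (i + 1L):length(groups)) {
      a <- features[features$group == groups[i], , drop = FALSE]
      b <- features[features$group == groups[j], , drop = FALSE]
      for (f in feat_order) {
        cmp <- anova_compare(a[[f]], b[[f]], quantity_name = f)
        rows[[length(rows) + 1L]] <-
          data.frame(group_a = groups[i], group_b = groups[j], quantity = f,
                     mean_a = cmp$mean_a, sd_a = cmp$sd_a,
                     mean_b = cmp$mean_b, sd_b = cmp$sd_b,
                     f_statistic = cmp$f_statistic, p_value = cmp$p_value,
                     stars = cmp$stars, stringsAsFactors = FALSE)
      }
      cmp <- anova_compare(per_unit_snr(a), per_unit_snr(b),
                           quantity_name = "snr_combined")
      rows[[length(rows) + 1L]] <-
        data.frame(group_a = groups[i], group_b = groups[j],
                   quantity = "snr_combined",
                   mean_a = cmp$mean_a, sd_a = cmp$sd_a,
                   mean_b = cmp$mean_b, sd_b = cmp$sd_b,
                   f_statistic = cmp$f_statistic, p_value = cmp$p_value,
                   stars = cmp$stars, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("group_report", "data.frame")
  out
}

#' Render a group report as plain text
#'
#' Formats a [summarize_groups()] report as a fixed-width table in the usual
#' "benchmark vs comparison, mean +/- sd, stars" layout, with a footer noting
#' the GLCM sampling offset used.
#'
#' @param report a `group_report`.
#' @param distance,angle the GLCM offset the features were computed at
#'   (footer note only).
#' @param file optional path; when given the text is also written there.
#' @return the formatted lines, invisibly; printed when `file` is NULL.
#' @export
format_report <- function(report, distance = 10, angle = 0, file = NULL) {
  fmt <- function(m, s) sprintf("%.4g ± %.3g", m, s)
  lines <- c(
    sprintf("%-12s %-12s %-14s %-22s %-22s %-8s %s",
            "group A", "group B", "quantity", "A (mean ± sd)",
            "B (mean ± sd)", "p", "sig"),
    strrep("-", 100))
  for (k in seq_len(nrow(report))) {
    r <- report[k, ]
    lines <- c(lines, sprintf("%-12s %-12s %-14s %-22s %-22s %-8.3g %s",
                              r$group_a, r$group_b, r$quantity,
                              fmt(r$mean_a, r$sd_a), fmt(r$mean_b, r$sd_b),
                              r$p_value, r$stars))
  }
  lines <- c(lines, "",
             sprintf("GLCM sampling offset was (%d.%d); group A is the benchmark.",
                     as.integer(distance), as.integer(angle)),
             "* p < 0.05, ** p < 0.01, *** p < 0.001.")
  if (!is.null(file)) writeLines(lines, file) else cat(lines, sep = "\n")
  invisible(lines)
}
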