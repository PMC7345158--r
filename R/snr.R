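#' Taguchi smaller-is-better signal-to-noise ratio
#'
#' `-10 log10( mean(y^2) )` in decibels: large when all values are small,
#' penalizing both level and spread of a quantity that should be minimized.
#'
#' @param values positive numeric vector.
#' @return S/N ratio in decibels.
#' @export
snr_smaller_is_better <- function(values) {
  check_snr_values(values)
  -10 * log10(mean(values^2))
}

#' Taguchi larger-is-better signal-to-noise ratio
#'
#' `-10 log10( mean(1/y^2) )` in decibels: large when all values are large.
#'
#' @param values positive numeric vector.
#' @return S/N ratio in decibels.
#' @export
snr_larger_is_better <- function(values) {
  check_snr_values(values)
  -10 * log10(mean(1 / values^2))
}

check_snr_values <- function(values) {
  if (length(values) < 1L) stop("`values` must be non-empty")
  if (anyNA(values) || any(values <= 0))
    stop("S/N ratios are defined for strictly positive values only")
  invisible(TRUE)
}

#' Default feature response directions
#'
#' Resistant-phenotype images show higher contrast and entropy (edges, 3-D
#' relief, disorder) and lower energy and homogeneity (less orderliness and
#' smoothness), so contrast and entropy are scored larger-is-better and
#' energy and homogeneity smaller-is-better.
#'
#' @return named character vector mapping feature name to direction.
#' @export
default_directions <- function() {
  c(contrast = "larger_is_better", entropy = "larger_is_better",
    energy = "smaller_is_better", homogeneity = "smaller_is_better")
}

#' Combined Taguchi S/N chemoresistance score for a group of patches
#'
#' Pools the raw values of the larger-is-better features (contrast, entropy)
#' into one larger-is-better S/N evaluation, the smaller-is-better features
#' (energy, homogeneity) into one smaller-is-better evaluation, and averages
#' the two components (`combiner = "pooled"`, the default). A higher combined
#' score means the images look more like the resistant phenotype. The
#' alternative `combiner = "per_feature"` computes one S/N per feature and
#' averages the four.
#'
#' Zero (or negative) values cannot enter an S/N ratio; patches contributing
#' such values to a pool are excluded from that pool and counted in
#' `n_excluded` (a perfectly uniform patch, for instance, has zero contrast
#' and zero entropy).
#'
#' @param features data.frame with columns `contrast`, `energy`,
#'   `homogeneity`, `entropy` (one row per patch), e.g. from
#'   [patch_features()].
#' @param directions named vector as from [default_directions()].
#' @param combiner `"pooled"` (default) or `"per_feature"`.
#' @param group_label free-text label stored with the result.
#' @return object of class `snr_result`: list with `snr_combined`,
#'   `snr_larger`, `snr_smaller`, `n_patches`, `n_excluded`, `combiner`,
#'   `group_label`.
#' @export
combined_snr <- function(features, directions = default_directions(),
                         combiner = c("pooled", "per_feature"),
                         group_label = "group") {
  combiner <- match.arg(combiner)
  need <- names(directions)
  if (!all(need %in% names(features)))
    stop("`features` must contain columns: ", paste(need, collapse = ", "))
  n <- nrow(features)
  if (is.null(n) || n < 1L) stop("`features` must have at least one row")
  larger_feats <- need[directions == "larger_is_better"]
  smaller_feats <- need[directions == "smaller_is_better"]
  pool_l <- unlist(features[larger_feats], use.names = FALSE)
  pool_s <- unlist(features[smaller_feats], use.names = FALSE)
  n_excluded <- sum(pool_l <= 0) + sum(pool_s <= 0)
  pool_l <- pool_l[pool_l > 0]
  pool_s <- pool_s[pool_s > 0]
  if (combiner == "pooled") {
    if (length(pool_l) == 0L || length(pool_s) == 0L)
      stop("all values excluded from an S/N pool; cannot score this group")
    snr_l <- snr_larger_is_better(pool_l)
    snr_s <- snr_smaller_is_better(pool_s)
    snr_c <- (snr_l + snr_s) / 2
  } else {
    per <- vapply(need, function(f) {
      v <- features[[f]]
      v <- v[v > 0]
      if (length(v) == 0L) return(NA_real_)
      if (directions[[f]] == "larger_is_better") snr_larger_is_better(v)
      else snr_smaller_is_better(v)
    }, numeric(1))
    if (anyNA(per)) stop("a feature had no positive values; cannot score")
    snr_l <- mean(per[larger_feats])
    snr_s <- mean(per[smaller_feats])
    snr_c <- mean(per)
  }
  structure(list(snr_combined = snr_c, snr_larger = snr_l,
                 snr_smaller = snr_s, n_patches = n,
                 n_excluded = n_excluded, combiner = combiner,
                 group_label = group_label),
            class = "snr_result")
}

#' @export
print.snr_result <- function(x, ...) {
  cat(sprintf(
    "<snr_result> %s: combined %.2f dB (larger %.2f, smaller %.2f), n = %d%s\n",
    x$group_label, x$snr_combined, x$snr_larger, x$snr_smaller, x$n_patches,
    if (x$n_excluded > 0) sprintf(", %d values excluded", x$n_excluded) else ""))
  invisible(x)
}

#' Group-level S/N summary with jackknife dispersion
#'
#' Computes the combined S/N of a group and a leave-one-patch-out jackknife
#' standard error of the combined score, giving the "mean +/- sd" style
#' summary used when reporting group S/N ratios.
#'
#' @inheritParams combined_snr
#' @return the [combined_snr()] result with an added `snr_sd` element
#'   (jackknife standard error; 0 when the group has a single patch).
#' @export
group_snr <- function(features, directions = default_directions(),
                      combiner = c("pooled", "per_feature"),
                      group_label = "group") {
  combiner <- match.arg(combiner)
  res <- combined_snr(features, directions, combiner, group_label)
  n <- nrow(features)
  if (n >= 2L) {
    loo <- vapply(seq_len(n), function(k) {
      combined_snr(features[-k, , drop = FALSE], directions, combiner,
                   group_label)$snr_combined
    }, numeric(1))
    res$snr_sd <- sqrt((n - 1) / n * sum((loo - mean(loo))^2))
  } else {
    res$snr_sd <- 0
  }
  res
}

#' Per-image combined S/N scores
#'
#' Splits a patch-level feature table by its `source_image` column and scores
#' each image separately, yielding one combined S/N value per image. These
#' per-image scores are the sampling units for group comparisons.
#'
#' @param features data.frame from [patch_features()] with a `source_image`
#'   column.
#' @inheritParams combined_snr
#' @return data.frame with columns `source_image` and `snr_combined`.
#' @export
per_image_snr <- function(features, directions = default_directions(),
                          combiner = c("pooled", "per_feature")) {
  combiner <- match.arg(combiner)
  if (!"source_image" %in% names(features))
    stop("`features` must have a `source_image` column")
  imgs <- unique(features$source_image)
  snr <- vapply(imgs, function(im) {
    combined_snr(features[features$source_image == im, , drop = FALSE],
                 directions, combiner, group_label = im)$snr_combined
  }, numeric(1))
  data.frame(source_image = imgs, snr_combined = unname(snr),
             stringsAsFactors = FALSE)
}
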