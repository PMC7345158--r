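#' Gray-level co-occurrence matrix of a patch
#'
#' Counts ordered pixel pairs `(p, q)` where `q` is displaced from `p` by the
#' given interpixel distance along the given angle, and normalizes the counts
#' by the number of pairs actually counted, so entries sum to 1. Angle
#' convention: 0 degrees points rightward along a row, 90 degrees upward
#' along a column (image-processing convention), so the row/column
#' displacement is `(-d sin(theta), d cos(theta))`. With `symmetric = TRUE`
#' (the default, and common GLCM practice) the reverse displacement is also
#' counted, which makes the matrix symmetric.
#'
#' The realized pair count shrinks as the distance grows; normalization
#' always divides by that realized count, never by a fixed constant, so
#' features stay comparable across distances.
#'
#' @param patch a [gray_patch()] (or an integer matrix plus `gray_levels`).
#' @param distance interpixel distance d >= 1, default 10.
#' @param angle one of 0, 45, 90, 135 (degrees), default 0.
#' @param symmetric count each pair in both directions; default TRUE.
#' @param gray_levels number of gray levels; taken from the patch when absent.
#' @return an object of class `glcm`: list with `C` (G x G probability
#'   matrix), `gray_levels`, `distance`, `angle`, `symmetric`, `pair_count`.
#' @export
compute_glcm <- function(patch, distance = 10L, angle = 0L,
                         symmetric = TRUE, gray_levels = NULL) {
  if (is.null(gray_levels)) gray_levels <- attr(patch, "gray_levels")
  if (is.null(gray_levels))
    stop("`gray_levels` must be supplied for a plain matrix")
  G <- as.integer(gray_levels)
  d <- as.integer(distance)
  if (d < 1L) stop("`distance` must be >= 1")
  if (!angle %in% c(0, 45, 90, 135))
    stop("`angle` must be one of 0, 45, 90, 135")
  m <- unclass(patch)
  nr <- nrow(m); nc <- ncol(m)
  disp <- switch(as.character(angle),
                 "0"   = c(0L, d),
                 "45"  = c(-d, d),
                 "90"  = c(-d, 0L),
                 "135" = c(-d, -d))
  dr <- disp[1L]; dc <- disp[2L]
  rows_p <- max(1L, 1L - dr):min(nr, nr - dr)
  cols_p <- max(1L, 1L - dc):min(nc, nc - dc)
  if (length(rows_p) < 1L || length(cols_p) < 1L ||
      rows_p[1] > rows_p[length(rows_p)] || cols_p[1] > cols_p[length(cols_p)])
    stop("offset distance too large: no valid pixel pairs")
  a <- m[rows_p, cols_p, drop = FALSE]
  b <- m[rows_p + dr, cols_p + dc, drop = FALSE]
  idx <- as.numeric(a) * G + as.numeric(b) + 1
  counts <- tabulate(idx, nbins = G * G)
  if (symmetric) counts <- counts + tabulate(as.numeric(b) * G +
                                               as.numeric(a) + 1,
                                             nbins = G * G)
  total <- sum(counts)
  if (total == 0) stop("offset distance too large: no valid pixel pairs")
  C <- matrix(counts / total, G, G, byrow = TRUE)  # idx built as i*G + j
  structure(list(C = C, gray_levels = G, distance = d, angle = angle,
                 symmetric = symmetric, pair_count = total),
            class = "glcm")
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("<glcm> G = %d, offset (%d, %d deg), %s, %d pairs\n",
              x$gray_levels, x$distance, x$angle,
              if (x$symmetric) "symmetric" else "asymmetric", x$pair_count))
  invisible(x)
}

#' Texture features of a co-occurrence matrix
#'
#' Computes the four scalar GLCM texture features:
#' \describe{
#'   \item{contrast}{\eqn{\sum_{ij} C_{ij} (i-j)^2} — local intensity
#'     variation across the offset; sensitive to edges and 3-D relief.}
#'   \item{energy}{\eqn{\sum_{ij} C_{ij}^2} — orderliness; 1 for a perfectly
#'     uniform patch.}
#'   \item{homogeneity}{\eqn{\sum_{ij} C_{ij} / (1 + |i-j|)} — concentration
#'     of mass near the diagonal, i.e. smoothness.}
#'   \item{entropy}{\eqn{-\sum_{ij} C_{ij} \log C_{ij}} — disorder of the
#'     co-occurrence distribution, with the `0 log 0 = 0` convention.}
#' }
#'
#' @param glcm a `glcm` from [compute_glcm()].
#' @param entropy_base base of the entropy logarithm, 2 (bits, default) or
#'   `exp(1)` (nats).
#' @return named list with `contrast`, `energy`, `homogeneity`, `entropy`.
#' @export
compute_features <- function(glcm, entropy_base = 2) {
  stopifnot(inherits(glcm, "glcm"))
  C <- glcm$C
  G <- glcm$gray_levels
  ij <- abs(outer(seq_len(G) - 1L, seq_len(G) - 1L, "-"))
  pos <- C[C > 0]
  list(
    contrast    = sum(C * ij^2),
    energy      = sum(C^2),
    homogeneity = sum(C / (1 + ij)),
    entropy     = -sum(pos * log(pos, base = entropy_base))
  )
}

#' Feature table for a set of patches
#'
#' Applies [compute_glcm()] and [compute_features()] to every patch at one
#' offset and collects the results in a data frame, one row per patch.
#'
#' @param patches list of [gray_patch()] objects.
#' @param distance,angle,symmetric,entropy_base see [compute_glcm()] and
#'   [compute_features()].
#' @param source_image optional character vector (length 1 or
#'   `length(patches)`) identifying each patch's source image.
#' @return data.frame with columns `patch_id`, `source_image`, `distance`,
#'   `angle`, `contrast`, `energy`, `homogeneity`, `entropy`.
#' @export
patch_features <- function(patches, distance = 10L, angle = 0L,
                           symmetric = TRUE, entropy_base = 2,
                           source_image = NA_character_) {
  if (length(patches) == 0L) stop("`patches` must be non-empty")
  src <- rep_len(source_image, length(patches))
  rows <- lapply(seq_along(patches), function(k) {
    f <- compute_features(compute_glcm(patches[[k]], distance, angle,
                                       symmetric),
                          entropy_base = entropy_base)
    o <- attr(patches[[k]], "origin")
    data.frame(patch_id = if (!is.null(o))
                 sprintf("r%d_c%d", o[1], o[2]) else as.character(k),
               source_image = src[k], distance = distance, angle = angle,
               contrast = f$contrast, energy = f$energy,
               homogeneity = f$homogeneity, entropy = f$entropy,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
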