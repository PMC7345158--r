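#' Texture features as a function of interpixel distance
#'
#' Recomputes the four GLCM features of every patch at each interpixel
#' distance and records the across-patch mean and standard deviation, giving
#' one curve per feature. Texture statistics change characteristically when
#' the distance approaches the dominant object size — here the 10–20 pixel
#' cell diameter — so these curves locate the scale of the cells.
#'
#' @param patches list of [gray_patch()] objects.
#' @param distances integer vector of distances, default `1:40`.
#' @param angle GLCM angle in degrees, default 0.
#' @param symmetric,entropy_base see [compute_glcm()], [compute_features()].
#' @param group_label free-text label stored with the profile.
#' @return object of class `sweep_profile`: data.frame with columns `group`,
#'   `feature`, `distance`, `mean`, `sd`.
#' @export
sweep_features <- function(patches, distances = 1:40, angle = 0L,
                           symmetric = TRUE, entropy_base = 2,
                           group_label = "group") {
  if (length(patches) == 0L) stop("`patches` must be non-empty")
  distances <- as.integer(distances)
  side <- min(vapply(patches, nrow, integer(1)))
  if (any(distances >= side))
    stop("all distances must be smaller than the patch side (", side, ")")
  feat_names <- c("contrast", "energy", "homogeneity", "entropy")
  rows <- lapply(distances, function(d) {
    vals <- vapply(patches, function(p) {
      f <- compute_features(compute_glcm(p, d, angle, symmetric),
                            entropy_base = entropy_base)
      unlist(f[feat_names])
    }, numeric(4))
    data.frame(group = group_label, feature = feat_names, distance = d,
               mean = rowMeans(vals),
               sd = apply(vals, 1, stats::sd),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  # sd of a single patch is NA; report 0 spread
  out$sd[is.na(out$sd)] <- 0
  class(out) <- c("sweep_profile", "data.frame")
  out
}

# 3-point moving average; endpoints kept as-is
smooth3 <- function(y) {
  n <- length(y)
  if (n < 3L) return(y)
  s <- y
  s[2:(n - 1)] <- (y[1:(n - 2)] + y[2:(n - 1)] + y[3:n]) / 3
  s
}

#' Locate the inflection distance of a feature curve
#'
#' Smooths the mean curve with a 3-point moving average, takes the discrete
#' second difference, and returns the distance at which it first changes
#' sign. When the second difference never changes sign (e.g. a straight
#' line), the distance of the largest absolute first difference is returned
#' instead and flagged with `inflection_found = FALSE`.
#'
#' @param profile a `sweep_profile` from [sweep_features()].
#' @param feature one of `"contrast"`, `"energy"`, `"homogeneity"`,
#'   `"entropy"`.
#' @param group which group to use when the profile holds several; default
#'   the first.
#' @return list with `distance` (integer), `inflection_found` (logical) and
#'   `feature`.
#' @export
find_inflection <- function(profile, feature, group = NULL) {
  stopifnot(inherits(profile, "data.frame"))
  feature <- match.arg(feature,
                       c("contrast", "energy", "homogeneity", "entropy"))
  if (is.null(group)) group <- profile$group[1]
  cur <- profile[profile$feature == feature & profile$group == group, ]
  cur <- cur[order(cur$distance), ]
  d <- cur$distance
  y <- cur$mean
  if (length(d) < 5L) stop("need at least 5 distances to locate an inflection")
  s <- smooth3(y)
  n <- length(s)
  dd <- s[3:n] - 2 * s[2:(n - 1)] + s[1:(n - 2)]  # at d[2:(n-1)]
  dd_dist <- d[2:(n - 1)]
  scale <- max(abs(dd), 1e-300)
  eps <- 1e-9 * scale
  sgn <- ifelse(abs(dd) <= eps, 0L, ifelse(dd > 0, 1L, -1L))
  nz <- which(sgn != 0L)
  if (length(nz) >= 1L) {
    first <- sgn[nz[1]]
    for (k in nz[-1]) {
      if (sgn[k] != first) {
        # crossing between the last same-signed point and k: report the
        # grid point with the smaller |second difference| (earlier on ties)
        prev <- max(which(sgn[seq_len(k - 1)] == first))
        cand <- prev:k
        best <- cand[which.min(abs(dd[cand]))]
        return(list(distance = dd_dist[best], inflection_found = TRUE,
                    feature = feature))
      }
    }
  }
  fd <- abs(diff(y))
  list(distance = d[which.max(fd)], inflection_found = FALSE,
       feature = feature)
}

#' Plot feature curves against interpixel distance
#'
#' Draws one panel per feature with mean +/- sd ribbons per group, using base
#' graphics. Intended for the synthetic study; safe on headless systems when
#' written to a PNG device.
#'
#' @param profile one or more row-bound `sweep_profile`s.
#' @param file optional PNG path; when given, the plot is written there.
#' @return invisibly, the profile.
#' @export
plot_sweep <- function(profile, file = NULL) {
  feats <- c("energy", "contrast", "homogeneity", "entropy")
  groups <- unique(profile$group)
  cols <- grDevices::hcl.colors(max(2L, length(groups)), "Dark 2")
  if (!is.null(file)) grDevices::png(file, width = 900, height = 700)
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit({
    graphics::par(op)
    if (!is.null(file)) grDevices::dev.off()
  }, add = TRUE)
  for (f in feats) {
    sub <- profile[profile$feature == f, ]
    ylim <- range(sub$mean - sub$sd, sub$mean + sub$sd)
    graphics::plot(NA, xlim = range(sub$distance), ylim = ylim,
                   xlab = "interpixel distance (px)", ylab = f, main = f)
    for (gi in seq_along(groups)) {
      g <- sub[sub$group == groups[gi], ]
      g <- g[order(g$distance), ]
      graphics::polygon(c(g$distance, rev(g$distance)),
                        c(g$mean - g$sd, rev(g$mean + g$sd)),
                        col = grDevices::adjustcolor(cols[gi], 0.2),
                        border = NA)
      graphics::lines(g$distance, g$mean, col = cols[gi], lwd = 2)
    }
    graphics::legend("topleft", legend = groups, col = cols[seq_along(groups)],
                     lwd = 2, bty = "n", cex = 0.8)
  }
  invisible(profile)
}
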