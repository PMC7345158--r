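# run expr with a local RNG state so callers' streams are untouched
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Generative parameters for one synthetic phenotype
#'
#' Describes how cells of one phenotype are rendered: geometry (cell count
#' and radius range), gray levels (cell interior and gap background),
#' interior roughness (a smoothed multiplicative speckle field emulating
#' rough 3-D surfaces), a bright rim annulus emulating the scattering /
#' defocus halo at cell margins, boundary softness, and additive sensor
#' noise.
#'
#' The two presets encode the optical signatures that distinguish the
#' phenotypes: wild-type (`"wt"`) cells are flat, smooth and in focus (weak
#' roughness, faint halo, softer edges), whereas cisplatin-resistant
#' (`"cp"`) cells pile into rough three-dimensional structures that scatter
#' light, giving strong interior speckle and bright enhanced margins.
#' Cell radii of 5–10 px give the 10–20 px diameters typical of ovarian
#' carcinoma cells at the working magnification. The default `n_cells` gives
#' a confluent monolayer on the 300 x 300 px canvas used throughout; scale
#' it with the canvas area for other sizes.
#'
#' @param phenotype `"wt"` or `"cp"` to start from a preset.
#' @param n_cells number of cells placed (overlap allowed).
#' @param radius_range numeric `(min, max)` cell radius in pixels.
#' @param interior_level mean gray level of cell bodies.
#' @param background_level mean gray level of the gaps.
#' @param roughness_amplitude speckle strength inside cells, gray levels.
#' @param speckle_scale correlation length of the speckle field, pixels.
#' @param halo_gain added brightness of the 2 px rim annulus, gray levels.
#' @param edge_softness Gaussian blur sigma applied to the composed scene,
#'   pixels; 0 disables.
#' @param noise_sd additive Gaussian sensor noise, gray levels.
#' @param seed integer seed fully determining the rendered image.
#' @return object of class `phenotype_params` (a named list).
#' @export
phenotype_params <- function(phenotype = c("wt", "cp"),
                             n_cells = NULL, radius_range = c(5, 10),
                             interior_level = NULL, background_level = 70,
                             roughness_amplitude = NULL, speckle_scale = 3,
                             halo_gain = NULL, edge_softness = NULL,
                             noise_sd = NULL, seed = 1L) {
  phenotype <- match.arg(phenotype)
  preset <- if (phenotype == "wt") {
    list(n_cells = 800L, interior_level = 150, roughness_amplitude = 5,
         halo_gain = 8, edge_softness = 1.5, noise_sd = 3)
  } else {
    list(n_cells = 800L, interior_level = 150, roughness_amplitude = 45,
         halo_gain = 50, edge_softness = 0.8, noise_sd = 6)
  }
  p <- list(
    phenotype = phenotype,
    n_cells = if (is.null(n_cells)) preset$n_cells else as.integer(n_cells),
    radius_range = as.numeric(radius_range),
    interior_level = if (is.null(interior_level)) preset$interior_level
                     else interior_level,
    background_level = background_level,
    roughness_amplitude = if (is.null(roughness_amplitude))
                            preset$roughness_amplitude
                          else roughness_amplitude,
    speckle_scale = speckle_scale,
    halo_gain = if (is.null(halo_gain)) preset$halo_gain else halo_gain,
    edge_softness = if (is.null(edge_softness)) preset$edge_softness
                    else edge_softness,
    noise_sd = if (is.null(noise_sd)) preset$noise_sd else noise_sd,
    seed = as.integer(seed))
  validate_phenotype_params(p)
  structure(p, class = "phenotype_params")
}

validate_phenotype_params <- function(p) {
  if (p$radius_range[1] < 2 || p$radius_range[2] < p$radius_range[1])
    stop("`radius_range` must satisfy min >= 2 and max >= min")
  if (p$n_cells < 0) stop("`n_cells` must be >= 0")
  levels <- c(p$interior_level, p$background_level,
              p$interior_level + p$halo_gain)
  if (any(levels < 0) || any(levels > 255))
    stop("expected gray levels must stay inside [0, 255]")
  if (p$roughness_amplitude < 0 || p$halo_gain < 0 || p$noise_sd < 0 ||
      p$edge_softness < 0 || p$speckle_scale < 0)
    stop("amplitude/noise/blur parameters must be >= 0")
  invisible(p)
}

#' @export
print.phenotype_params <- function(x, ...) {
  cat(sprintf(paste0("<phenotype_params> %s: %d cells, r in [%g, %g] px, ",
                     "interior %g on background %g, roughness %g ",
                     "(scale %g px), halo %g, edge blur %g px, noise sd %g, ",
                     "seed %d\n"),
              x$phenotype, x$n_cells, x$radius_range[1], x$radius_range[2],
              x$interior_level, x$background_level, x$roughness_amplitude,
              x$speckle_scale, x$halo_gain, x$edge_softness, x$noise_sd,
              x$seed))
  invisible(x)
}

#' Render one synthetic cell-monolayer image
#'
#' Places `n_cells` disks with centers uniform over the canvas (overlap
#' allowed) and radii uniform in `radius_range`. Disk interiors take
#' `interior_level` modulated by a multiplicative speckle field — low-pass
#' filtered unit-variance Gaussian noise with correlation length
#' `speckle_scale`, scaled to `roughness_amplitude` gray levels. A rim
#' annulus of width 2 px is brightened by `halo_gain`, the composed scene is
#' blurred with sigma `edge_softness`, Gaussian noise of sd `noise_sd` is
#' added, and the result is clipped to `[0, 255]` and rounded. The image is
#' fully determined by `params$seed`.
#'
#' @param params a [phenotype_params()].
#' @param height,width canvas size in pixels; must be at least twice the
#'   maximum cell radius. Default 300 x 300, the size used by the package's
#'   simulated studies.
#' @return an 8-bit [gray_image()].
#' @export
render_monolayer <- function(params, height = 300L, width = 300L) {
  stopifnot(inherits(params, "phenotype_params"))
  validate_phenotype_params(params)
  height <- as.integer(height); width <- as.integer(width)
  if (min(height, width) < 2 * params$radius_range[2])
    stop("canvas must be at least twice the maximum cell radius")
  with_local_seed(params$seed, {
    canvas <- matrix(params$background_level, height, width)
    inside <- matrix(FALSE, height, width)
    rim <- matrix(FALSE, height, width)
    n <- params$n_cells
    if (n > 0) {
      cy <- stats::runif(n, 1, height)
      cx <- stats::runif(n, 1, width)
      r <- stats::runif(n, params$radius_range[1], params$radius_range[2])
      for (k in seq_len(n)) {
        r0 <- max(1L, floor(cy[k] - r[k] - 2)); r1 <- min(height, ceiling(cy[k] + r[k] + 2))
        c0 <- max(1L, floor(cx[k] - r[k] - 2)); c1 <- min(width, ceiling(cx[k] + r[k] + 2))
        yy <- r0:r1; xx <- c0:c1
        dist <- sqrt(outer((yy - cy[k])^2, (xx - cx[k])^2, "+"))
        inside[yy, xx] <- inside[yy, xx] | (dist <= r[k])
        rim[yy, xx] <- rim[yy, xx] | (abs(dist - r[k]) <= 1)
      }
      canvas[inside] <- params$interior_level
      if (params$roughness_amplitude > 0) {
        s <- matrix(stats::rnorm(height * width), height, width)
        if (params$speckle_scale > 0)
          s <- EBImage::gblur(s, sigma = params$speckle_scale)
        s <- (s - mean(s)) / stats::sd(s)
        mod <- 1 + (params$roughness_amplitude / params$interior_level) * s
        canvas[inside] <- params$interior_level * mod[inside]
      }
      if (params$halo_gain > 0)
        canvas[rim] <- canvas[rim] + params$halo_gain
    }
    if (params$edge_softness > 0)
      canvas <- EBImage::gblur(canvas, sigma = params$edge_softness)
    if (params$noise_sd > 0)
      canvas <- canvas + matrix(stats::rnorm(height * width,
                                             sd = params$noise_sd),
                                height, width)
    canvas <- pmin(pmax(round(canvas), 0), 255)
    gray_image(matrix(as.integer(canvas), height, width), bit_depth = 8L)
  })
}

# derived per-image seed: a fixed integer mix of (master seed, group, index)
derive_seed <- function(master, group_idx, image_idx) {
  as.integer((as.numeric(master %% 2147483647L) * 69069 +
                group_idx * 1000003 + image_idx * 10007) %% 2147483647)
}

#' Generate a paired two-phenotype synthetic study
#'
#' Renders `n_images_per_group` images for each phenotype with per-image
#' seeds derived deterministically from the master seed, the group index and
#' the image index, so each group is reproducible independently. With the
#' default presets the group means at offset (10, 0 deg) order as in real
#' resistant-vs-wild-type comparisons: contrast and entropy higher for the
#' resistant-like group, energy and homogeneity lower.
#'
#' @param n_images_per_group images per phenotype, >= 1.
#' @param wt_params,cp_params [phenotype_params()] for the two groups.
#' @param seed master seed.
#' @param height,width canvas size per image.
#' @return object of class `synthetic_dataset`: list with `images` (list of
#'   [gray_image()]), `labels` (character), `image_ids`, `params_used`
#'   (named list of the two parameter sets), `image_seeds`, `seed`.
#' @export
generate_study <- function(n_images_per_group = 20L,
                           wt_params = phenotype_params("wt"),
                           cp_params = phenotype_params("cp"),
                           seed = 1L, height = 300L, width = 300L) {
  n <- as.integer(n_images_per_group)
  if (n < 1L) stop("`n_images_per_group` must be >= 1")
  groups <- list(WT = wt_params, CP = cp_params)
  images <- list(); labels <- character(0); ids <- character(0)
  seeds <- integer(0)
  for (gi in seq_along(groups)) {
    for (k in seq_len(n)) {
      p <- groups[[gi]]
      p$seed <- derive_seed(seed, gi, k)
      images[[length(images) + 1L]] <- render_monolayer(p, height, width)
      labels <- c(labels, names(groups)[gi])
      ids <- c(ids, sprintf("%s_%03d", names(groups)[gi], k))
      seeds <- c(seeds, p$seed)
    }
  }
  structure(list(images = images, labels = labels, image_ids = ids,
                 params_used = groups, image_seeds = seeds,
                 seed = as.integer(seed)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d images (%s), seed %d, %d x %d px\n",
              length(x$images),
              paste(sprintf("%s: %d", names(table(x$labels)),
                            table(x$labels)), collapse = ", "),
              x$seed, nrow(x$images[[1]]), ncol(x$images[[1]])))
  invisible(x)
}

#' Patch-level feature table for a whole dataset
#'
#' Quantizes every image, tiles it into patches and computes the four GLCM
#' features at one offset, returning a single table with `group` and
#' `source_image` columns ready for [summarize_groups()] and
#' [per_image_snr()]. Synthetic frames are confluent, so no foreground
#' filtering is applied by default.
#'
#' @param dataset a `synthetic_dataset`, or a list with `images`, `labels`
#'   and optionally `image_ids`.
#' @param gray_levels,side,min_foreground_fraction,threshold see
#'   [quantize()] and [extract_patches()].
#' @param distance,angle,symmetric,entropy_base see [compute_glcm()].
#' @return data.frame: [patch_features()] columns plus `group`.
#' @export
study_feature_table <- function(dataset, gray_levels = 256L, side = 150L,
                                min_foreground_fraction = 0,
                                threshold = 5L,
                                distance = 10L, angle = 0L,
                                symmetric = TRUE, entropy_base = 2) {
  ids <- dataset$image_ids
  if (is.null(ids)) ids <- sprintf("img_%03d", seq_along(dataset$images))
  tabs <- lapply(seq_along(dataset$images), function(k) {
    img <- quantize(dataset$images[[k]], gray_levels)
    patches <- extract_patches(img, side, min_foreground_fraction, threshold)
    if (length(patches) == 0L) return(NULL)
    tab <- patch_features(patches, distance, angle, symmetric, entropy_base,
                          source_image = ids[k])
    tab$group <- dataset$labels[k]
    tab
  })
  out <- do.call(rbind, tabs)
  if (is.null(out)) stop("no patches passed the foreground filter")
  out
}

#' Write a synthetic dataset to disk
#'
#' Writes each image as an 8-bit PNG, a `labels.csv` (image path, phenotype,
#' per-image seed) and a `manifest.txt` recording the full generative
#' parameters.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return paths of the written image files, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(dataset$images), function(k) {
    path <- file.path(dir, paste0(dataset$image_ids[k], ".png"))
    png::writePNG(unclass(dataset$images[[k]]) / 255, path)
    path
  }, character(1))
  utils::write.csv(
    data.frame(image = basename(paths), phenotype = dataset$labels,
               seed = dataset$image_seeds, stringsAsFactors = FALSE),
    file.path(dir, "labels.csv"), row.names = FALSE)
  man <- c(sprintf("master_seed: %d", dataset$seed),
           sprintf("images_per_group: %d", sum(dataset$labels ==
                                                 dataset$labels[1])),
           "",
           unlist(lapply(names(dataset$params_used), function(g) {
             p <- dataset$params_used[[g]]
             c(sprintf("[%s]", g),
               vapply(setdiff(names(p), "phenotype"), function(f)
                 sprintf("%s: %s", f, paste(p[[f]], collapse = ", ")),
                 character(1)),
               "")
           })))
  writeLines(man, file.path(dir, "manifest.txt"))
  invisible(paths)
}
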