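#' Construct a grayscale image object
#'
#' A `gray_image` is an integer pixel matrix (rows x columns) carrying its
#' bit depth and, after quantization, the number of gray levels actually in
#' use. Pixel values must lie in `[0, 2^bit_depth - 1]`.
#'
#' @param pixels integer matrix of pixel values.
#' @param bit_depth integer, 8 or 16.
#' @param gray_levels number of gray levels the values are drawn from;
#'   defaults to `2^bit_depth`.
#' @return an object of class `gray_image`.
#' @export
gray_image <- function(pixels, bit_depth = 8L, gray_levels = 2L^bit_depth) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  storage.mode(pixels) <- "integer"
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) stop("image must be non-empty")
  if (anyNA(pixels) || min(pixels) < 0L)
    stop("pixel values must be non-negative")
  if (max(pixels) >= 2^bit_depth)
    stop("pixel values exceed the stated bit depth")
  structure(pixels,
            bit_depth = as.integer(bit_depth),
            gray_levels = as.integer(gray_levels),
            class = c("gray_image", "matrix", "array"))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, %d-bit, %d gray levels, range [%d, %d]\n",
              nrow(x), ncol(x), attr(x, "bit_depth"),
              attr(x, "gray_levels"), min(x), max(x)))
  invisible(x)
}

# bit depth of a PNG file, from the IHDR chunk (byte 25 of the stream)
png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 26L)
  if (length(hdr) < 26L ||
      !identical(hdr[1:8],
                 as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))))
    stop("not a PNG file: ", path)
  as.integer(hdr[25L])
}

#' Read a grayscale microscopy image
#'
#' Reads an 8- or 16-bit PNG or TIFF as a `gray_image`. RGB images are
#' converted to luminance with the Rec. 601 weights (0.299, 0.587, 0.114);
#' this is a convenience path, since monochrome cameras write single-channel
#' files. An alpha channel, if present, is ignored.
#'
#' @param path path to a PNG or TIFF file.
#' @return a [gray_image()] with `bit_depth` matching the file.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    depth <- png_bit_depth(path)
    if (!depth %in% c(8L, 16L))
      stop("unsupported PNG bit depth: ", depth,
           " (only 8- and 16-bit grayscale/RGB supported)")
    arr <- png::readPNG(path)        # scaled to [0, 1]
    arr <- arr * (2^depth - 1)
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    depth <- as.integer(attr(arr, "bits.per.sample"))
    fmt <- attr(arr, "sample.format")
    if (!is.null(fmt) && !identical(fmt, "uint"))
      stop("unsupported TIFF sample format: ", fmt)
    if (!depth %in% c(8L, 16L))
      stop("unsupported TIFF bit depth: ", depth)
  } else {
    stop("unsupported file type: .", ext, " (expected PNG or TIFF)")
  }
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3L]
    if (nch >= 3L) {
      arr <- 0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L]
    } else {
      arr <- arr[, , 1L]            # gray + alpha
    }
  }
  gray_image(matrix(as.integer(round(arr)), nrow(arr), ncol(arr)),
             bit_depth = depth)
}

#' Quantize an image to G gray levels
#'
#' Maps each pixel `p` to `floor(p * G / 2^bit_depth)` so the output values
#' lie in `[0, G - 1]`. An 8-bit image with `G = 256` is returned unchanged.
#' Rescaling uses the fixed bit depth, never the per-image min/max, so
#' absolute brightness differences between experimental groups survive
#' quantization.
#'
#' @param image a [gray_image()].
#' @param gray_levels target number of gray levels G (>= 2), default 256.
#' @return a `gray_image` with values in `[0, G - 1]` and
#'   `gray_levels = G`.
#' @export
quantize <- function(image, gray_levels = 256L) {
  stopifnot(inherits(image, "gray_image"))
  G <- as.integer(gray_levels)
  if (is.na(G) || G < 2L) stop("`gray_levels` must be an integer >= 2")
  depth <- attr(image, "bit_depth")
  # already expressed on G levels (e.g. 8-bit input with G = 256, or a
  # previously quantized image): quantization is a no-op, so the map is
  # idempotent
  if (identical(attr(image, "gray_levels"), G)) return(image)
  px <- unclass(image)
  q <- matrix(as.integer(floor(as.numeric(px) * G / 2^depth)),
              nrow(px), ncol(px))
  gray_image(q, bit_depth = depth, gray_levels = G)
}

#' Construct a square analysis patch
#'
#' @param pixels square integer matrix with values in `[0, gray_levels - 1]`.
#' @param gray_levels number of gray levels G.
#' @param origin integer `(row, col)` of the top-left corner in the source
#'   image, 0-based.
#' @return an object of class `gray_patch`.
#' @export
gray_patch <- function(pixels, gray_levels, origin = c(0L, 0L)) {
  if (!is.matrix(pixels) || nrow(pixels) != ncol(pixels))
    stop("`pixels` must be a square matrix")
  storage.mode(pixels) <- "integer"
  G <- as.integer(gray_levels)
  if (min(pixels) < 0L || max(pixels) > G - 1L)
    stop("patch values must lie in [0, gray_levels - 1]")
  structure(pixels,
            gray_levels = G,
            origin = as.integer(origin),
            side = nrow(pixels),
            class = c("gray_patch", "matrix", "array"))
}

#' @export
print.gray_patch <- function(x, ...) {
  o <- attr(x, "origin")
  cat(sprintf("<gray_patch> %d x %d, G = %d, origin (%d, %d)\n",
              nrow(x), ncol(x), attr(x, "gray_levels"), o[1], o[2]))
  invisible(x)
}

#' Tile an image into square patches
#'
#' Cuts non-overlapping `side` x `side` tiles on a regular grid anchored at
#' the top-left corner, in row-major order. Tiles that are mostly empty
#' background are dropped: the background level is estimated as the modal
#' gray value of the whole image, a pixel counts as foreground when it
#' differs from that level by more than `threshold`, and a tile is kept only
#' if its foreground fraction reaches `min_foreground_fraction`.
#'
#' @param image a quantized [gray_image()].
#' @param side patch edge length in pixels, default 150.
#' @param min_foreground_fraction minimum fraction of foreground pixels for
#'   a tile to be kept; default 0.2. Use 0 to keep every tile.
#' @param threshold gray-level difference from the modal background beyond
#'   which a pixel counts as foreground; default 5.
#' @return list of [gray_patch()] objects, row-major, possibly empty.
#' @export
extract_patches <- function(image, side = 150L,
                            min_foreground_fraction = 0.2,
                            threshold = 5L) {
  stopifnot(inherits(image, "gray_image"))
  side <- as.integer(side)
  h <- nrow(image); w <- ncol(image)
  if (side < 1L || side > min(h, w))
    stop("`side` must be between 1 and the smaller image dimension")
  if (min_foreground_fraction < 0 || min_foreground_fraction > 1)
    stop("`min_foreground_fraction` must be in [0, 1]")
  G <- attr(image, "gray_levels")
  px <- unclass(image)
  mode_level <- as.integer(names(which.max(table(px))))
  fg <- abs(px - mode_level) > threshold
  n_r <- h %/% side
  n_c <- w %/% side
  out <- list()
  for (r in seq_len(n_r)) {
    for (cc in seq_len(n_c)) {
      rows <- ((r - 1L) * side + 1L):(r * side)
      cols <- ((cc - 1L) * side + 1L):(cc * side)
      if (mean(fg[rows, cols]) >= min_foreground_fraction) {
        out[[length(out) + 1L]] <-
          gray_patch(px[rows, cols, drop = FALSE], gray_levels = G,
                     origin = c((r - 1L) * side, (cc - 1L) * side))
      }
    }
  }
  out
}

#' Write patches as 8-bit PNG files
#'
#' Each patch is written as `<stem>_r<row>_c<col>.png`, where row/col are the
#' 0-based pixel origin of the patch in its source image. Patch values are
#' rescaled from `[0, G - 1]` to the 8-bit range.
#'
#' @param patches list of [gray_patch()] objects.
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @return character vector of written paths, invisibly.
#' @export
write_patches <- function(patches, dir, stem = "patch") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(patches))
  for (k in seq_along(patches)) {
    p <- patches[[k]]
    o <- attr(p, "origin")
    G <- attr(p, "gray_levels")
    paths[k] <- file.path(dir, sprintf("%s_r%d_c%d.png", stem, o[1], o[2]))
    png::writePNG(unclass(p) / (G - 1), paths[k])
  }
  invisible(paths)
}
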