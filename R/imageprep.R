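#' Read an RGB image from disk
#'
#' Reads an 8-bit PNG or TIFF image and returns it as an integer array with
#' values in \[0, 255\]. Grayscale files are expanded to three identical
#' channels so that every downstream stage can assume RGB input. Images with
#' higher bit depth are rescaled to 8 bits with a warning.
#'
#' @param path Path to a PNG or TIFF file.
#' @return An `H x W x 3` integer array with values in \[0, 255\].
#' @seealso [write_mask()], [to_grayscale()]
#' @export
read_image <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    stop("`path` must be a single file path")
  }
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: file not found: '%s'", path))
  }
  img <- tryCatch(
    EBImage::readImage(path),
    error = function(e) stop(sprintf("cannot read image '%s': %s", path, conditionMessage(e)))
  )
  px <- EBImage::imageData(img)
  # EBImage stores intensities in [0,1] with dims (x, y[, channel])
  if (max(px) > 1 + 1e-9) {
    warning(sprintf("image '%s' exceeds 8-bit range; rescaling to [0, 255]", path))
    px <- px / max(px)
  }
  v <- as.integer(round(pmin(pmax(px, 0), 1) * 255))
  if (length(dim(px)) == 2L) {
    g <- t(matrix(v, nrow(px), ncol(px)))
    out <- array(0L, c(nrow(g), ncol(g), 3L))
    out[, , 1L] <- g; out[, , 2L] <- g; out[, , 3L] <- g
  } else {
    nch <- dim(px)[3L]
    if (nch < 3L) stop(sprintf("image '%s' has %d channels; need 1 or >= 3", path, nch))
    out <- array(0L, c(dim(px)[2L], dim(px)[1L], 3L))
    a <- array(v, dim(px))
    for (ch in 1:3) out[, , ch] <- t(a[, , ch])
  }
  out
}

#' Write a binary mask as an 8-bit PNG
#'
#' Foreground pixels are written as 255, background as 0.
#'
#' @param path Output path (PNG).
#' @param mask Logical matrix (`H x W`).
#' @return Invisibly, `path`.
#' @export
write_mask <- function(path, mask) {
  stopifnot(is.matrix(mask))
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop(sprintf("cannot write mask: directory does not exist: '%s'", dir))
  }
  img <- EBImage::Image(t(mask * 1))
  EBImage::writeImage(img, path, type = "png", bits.per.sample = 8L)
  invisible(path)
}

#' Write a grayscale or RGB integer image as 8-bit PNG
#'
#' @param path Output path (PNG).
#' @param img Integer matrix (`H x W`) or array (`H x W x 3`) in \[0, 255\].
#' @return Invisibly, `path`.
#' @export
write_image <- function(path, img) {
  stopifnot(is.numeric(img))
  if (is.matrix(img)) {
    e <- EBImage::Image(t(img) / 255)
  } else if (length(dim(img)) == 3L) {
    a <- array(0, c(dim(img)[2L], dim(img)[1L], dim(img)[3L]))
    for (ch in seq_len(dim(img)[3L])) a[, , ch] <- t(img[, , ch])
    e <- EBImage::Image(a / 255, colormode = "Color")
  } else {
    stop("`img` must be an H x W matrix or H x W x C array")
  }
  EBImage::writeImage(e, path, type = "png", bits.per.sample = 8L)
  invisible(path)
}

#' Convert an RGB image to grayscale
#'
#' Uses the ITU-R BT.601 luminance weights (0.299, 0.587, 0.114), rounding to
#' the nearest integer. On inputs with R = G = B the conversion is the
#' identity.
#'
#' @param img `H x W x 3` integer array with values in \[0, 255\].
#' @return `H x W` integer matrix with values in \[0, 255\].
#' @export
to_grayscale <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3L] < 3L) {
    stop("`img` must be an H x W x 3 array")
  }
  if (any(dim(img)[1:2] < 1L)) stop("empty image")
  g <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
  g <- round(g)
  g[g < 0] <- 0; g[g > 255] <- 255
  matrix(as.integer(g), dim(img)[1L], dim(img)[2L])
}

#' Contrast-limited adaptive histogram equalisation (CLAHE)
#'
#' Tile-wise histogram equalisation with a clipping ceiling on histogram
#' bins, the standard pre-processing step that evens out stain intensity
#' before threshold search. `clip_limit` is the normalised ceiling: the
#' maximum fraction of a tile's pixels allowed in one histogram bin before
#' the excess is redistributed.
#'
#' @param img `H x W` integer matrix in \[0, 255\].
#' @param clip_limit Normalised clip limit, > 0. Default 0.01.
#' @param tile_grid Integer vector `c(rows, cols)` of tiles. Default `c(8, 8)`.
#' @return `H x W` integer matrix in \[0, 255\].
#' @export
enhance_contrast <- function(img, clip_limit = 0.01, tile_grid = c(8, 8)) {
  stopifnot(is.matrix(img))
  if (!is.numeric(clip_limit) || length(clip_limit) != 1L || clip_limit <= 0) {
    stop("`clip_limit` must be a positive number")
  }
  if (length(tile_grid) != 2L || any(tile_grid < 1)) {
    stop("`tile_grid` must be two positive integers")
  }
  if (length(unique(as.vector(img))) == 1L) {
    return(img)  # nothing to equalise
  }
  bins <- 256L
  # EBImage's limit is in multiples of the mean bin count; the normalised
  # fraction-of-tile-pixels convention converts as limit * bins.
  e <- EBImage::clahe(
    EBImage::Image(t(img) / 255),
    nx = as.integer(tile_grid[2L]), ny = as.integer(tile_grid[1L]),
    bins = bins, limit = clip_limit * bins, keep.range = FALSE
  )
  out <- round(t(EBImage::imageData(e)) * 255)
  out[out < 0] <- 0; out[out > 255] <- 255
  matrix(as.integer(out), nrow(img), ncol(img))
}

#' Pre-process an RGB image for threshold search
#'
#' Grayscale conversion followed by CLAHE; the result is the image whose
#' histogram drives the swarm threshold search and to which the thresholds
#' are applied.
#'
#' @inheritParams to_grayscale
#' @inheritParams enhance_contrast
#' @return `H x W` integer matrix in \[0, 255\].
#' @export
preprocess_image <- function(img, clip_limit = 0.01, tile_grid = c(8, 8)) {
  enhance_contrast(to_grayscale(img), clip_limit, tile_grid)
}
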