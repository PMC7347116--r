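# Slide-image I/O and resampling.
#
# Coordinate convention (package-wide): pixels are 0-based with
# x = column, y = row; pixel centers sit at integer coordinates. Images are
# R matrices with nrow = height and ncol = width, holding integer
# intensities in [0, 255].

#' Construct a slide image
#'
#' A single-channel 8-bit grayscale histological section image with its
#' physical resolution and identity. Intensities must be integers in
#' `[0, 255]`.
#'
#' @param pixels Numeric matrix of integer intensities in `[0, 255]`
#'   (`nrow` = height, `ncol` = width).
#' @param microns_per_pixel Physical resolution, microns per pixel
#'   (target 1.0 for this pipeline).
#' @param slide_id,slice_id Identifiers for the slide and the testis slice.
#' @return An object of class `slide_image`.
#' @export
slide_image <- function(pixels, microns_per_pixel = 1,
                        slide_id = "slide", slice_id = "slice") {
  if (!is.matrix(pixels) || nrow(pixels) < 1 || ncol(pixels) < 1)
    stop("`pixels` must be a matrix with both dimensions >= 1")
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 255) ||
      any(pixels != round(pixels)))
    stop("intensities must be integers in [0, 255]")
  check_scalar_num(microns_per_pixel, "microns_per_pixel", min = 1e-12)
  structure(list(pixels = pixels,
                 microns_per_pixel = as.numeric(microns_per_pixel),
                 slide_id = as.character(slide_id),
                 slice_id = as.character(slice_id)),
            class = "slide_image")
}

#' @export
print.slide_image <- function(x, ...) {
  cat(sprintf("<slide_image> %s/%s: %d x %d px at %.3g um/px\n",
              x$slide_id, x$slice_id, ncol(x$pixels), nrow(x$pixels),
              x$microns_per_pixel))
  invisible(x)
}

#' @export
dim.slide_image <- function(x) dim(x$pixels)

# Separable box-filter (area-averaging) resampling weights mapping n_in
# samples onto n_out samples. Each output pixel averages the input interval
# it covers, with fractional weights at the interval edges.
box_weights <- function(n_in, n_out) {
  W <- matrix(0, n_out, n_in)
  ratio <- n_in / n_out
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * ratio
    hi <- i * ratio
    j0 <- floor(lo)
    j1 <- min(ceiling(hi), n_in)
    for (j in seq(j0, j1 - 1)) {
      w <- min(hi, j + 1) - max(lo, j)
      if (w > 0) W[i, j + 1] <- w
    }
    W[i, ] <- W[i, ] / sum(W[i, ])
  }
  W
}

box_resample <- function(m, n_row_out, n_col_out) {
  if (n_row_out == nrow(m) && n_col_out == ncol(m)) return(m)
  Wr <- box_weights(nrow(m), n_row_out)
  Wc <- box_weights(ncol(m), n_col_out)
  Wr %*% m %*% t(Wc)
}

# ITU-R BT.601 luma weights for grayscale conversion.
luma601 <- c(0.299, 0.587, 0.114)

#' Load a slide image from a PNG file
#'
#' Reads a PNG, converts color images to single-channel grayscale using
#' ITU-R BT.601 luma weights, and resamples with an area-averaging box
#' filter so that the output resolution equals `target_microns_per_pixel`.
#' Intensities are quantized to integers and clamped to `[0, 255]` after
#' resampling.
#'
#' @param path Path to a PNG file (any bit depth / channel count readable
#'   by [png::readPNG()]).
#' @param source_microns_per_pixel Physical resolution of the file.
#' @param target_microns_per_pixel Desired output resolution (default 1).
#' @param slide_id,slice_id Identifiers recorded on the result.
#' @return A [slide_image()].
#' @export
load_slide_image <- function(path, source_microns_per_pixel = 1,
                             target_microns_per_pixel = 1,
                             slide_id = basename(path), slice_id = "slice") {
  check_scalar_num(source_microns_per_pixel, "source_microns_per_pixel",
                   min = 1e-12)
  check_scalar_num(target_microns_per_pixel, "target_microns_per_pixel",
                   min = 1e-12)
  if (!file.exists(path)) stop("cannot read image: file not found: ", path)
  arr <- tryCatch(png::readPNG(path),
                  error = function(e) stop("cannot decode PNG '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  gray <- if (length(dim(arr)) == 2) {
    arr * 255
  } else {
    nc <- dim(arr)[3]
    if (nc >= 3) {
      arr[, , 1] * luma601[1] * 255 + arr[, , 2] * luma601[2] * 255 +
        arr[, , 3] * luma601[3] * 255
    } else {
      arr[, , 1] * 255  # gray + alpha
    }
  }
  scale <- source_microns_per_pixel / target_microns_per_pixel
  out_dim <- pmax(1L, as.integer(round(dim(gray) * scale)))
  res <- box_resample(gray, out_dim[1], out_dim[2])
  slide_image(clamp255(round(res)), target_microns_per_pixel,
              slide_id = slide_id, slice_id = slice_id)
}

#' Write a slide image (or any 0-255 matrix) to an 8-bit grayscale PNG
#'
#' @param image A [slide_image()] or a numeric matrix of intensities in
#'   `[0, 255]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_slide_image <- function(image, path) {
  m <- if (inherits(image, "slide_image")) image$pixels else image
  png::writePNG(m / 255, path)
  invisible(path)
}
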