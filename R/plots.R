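# Diagnostic graphics: detection overlays and grid-search heat plots.

# draw a closed polygon outline onto an H x W x 3 array in a given color
draw_polygon_rgb <- function(arr, poly, rgb) {
  H <- dim(arr)[1]; W <- dim(arr)[2]
  n <- nrow(poly)
  if (n == 1) {
    x <- round(poly[1, 1]) + 1; y <- round(poly[1, 2]) + 1
    if (x >= 1 && x <= W && y >= 1 && y <= H)
      for (k in 1:3) arr[y, x, k] <- rgb[k]
    return(arr)
  }
  for (i in seq_len(n)) {
    j <- i %% n + 1
    steps <- max(2, ceiling(2 * max(abs(poly[j, ] - poly[i, ]))))
    t <- seq(0, 1, length.out = steps)
    xs <- round(poly[i, 1] + t * (poly[j, 1] - poly[i, 1])) + 1
    ys <- round(poly[i, 2] + t * (poly[j, 2] - poly[i, 2])) + 1
    keep <- xs >= 1 & xs <= W & ys >= 1 & ys <= H
    for (k in 1:3) arr[cbind(ys[keep], xs[keep], k)] <- rgb[k]
  }
  arr
}

#' Write a detection overlay PNG
#'
#' Superimposes results on the original image: matched detections are
#' outlined in green, missed annotations (false negatives) in red, and
#' unmatched detections (false positives) in yellow.
#'
#' @param image A [slide_image()].
#' @param detections An `mng_detections`.
#' @param annotations List of [mng_annotation()].
#' @param path Output PNG path.
#' @return The confusion counts of the match, invisibly.
#' @export
write_overlay <- function(image, detections, annotations, path) {
  cc <- match_detections(detections, annotations, dim(image))
  m <- image$pixels / 255
  arr <- array(rep(m, 3), c(dim(m), 3))
  matched <- attr(cc, "matches")
  for (i in seq_along(detections$regions)) {
    col <- if (i %in% matched$detection) c(0, 0.8, 0) else c(1, 0.9, 0)
    arr <- draw_polygon_rgb(arr, detections$regions[[i]]$boundary_polygon,
                            col)
  }
  for (j in seq_along(annotations))
    if (!j %in% matched$annotation)
      arr <- draw_polygon_rgb(arr, annotations[[j]]$polygon, c(0.9, 0, 0))
  png::writePNG(arr, path)
  invisible(cc)
}

#' Plot a grid-search F1 surface
#'
#' Draws the test-set F1 over (brightness, area) for one epoch as a heat
#' image, with F1 values below `floor` shown black and the selected
#' optimum boxed.
#'
#' @param result A `grid_search_result`.
#' @param epoch Epoch to plot (default: the optimal epoch).
#' @param floor Color-scale floor for F1 (default 0.65).
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the matrix of F1 values plotted.
#' @export
plot_grid_f1 <- function(result, epoch = result$optimal$epoch,
                         floor = 0.65, ...) {
  g <- result$grid[result$grid$epoch == epoch, ]
  bs <- sort(unique(g$brightness)); as_ <- sort(unique(g$area))
  z <- matrix(NA_real_, length(bs), length(as_))
  for (r in seq_len(nrow(g)))
    z[match(g$brightness[r], bs), match(g$area[r], as_)] <- g$f1[r]
  zc <- pmax(z, floor)
  graphics::image(x = seq_along(bs), y = seq_along(as_), z = zc,
                  col = grDevices::hcl.colors(64, "inferno"),
                  xlab = "cutoff brightness", ylab = "cutoff area",
                  axes = FALSE, ...)
  graphics::axis(1, at = seq_along(bs), labels = bs)
  graphics::axis(2, at = seq_along(as_), labels = as_)
  if (epoch == result$optimal$epoch) {
    graphics::rect(match(result$optimal$brightness, bs) - 0.5,
                   match(result$optimal$area, as_) - 0.5,
                   match(result$optimal$brightness, bs) + 0.5,
                   match(result$optimal$area, as_) + 0.5,
                   border = "black", lwd = 2)
  }
  invisible(z)
}
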