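# Heatmap post-processing: brightness cutoff, connected components,
# boundary tracing and Green's-theorem area filtering.

#' Apply a brightness cutoff to a heatmap
#'
#' Pixels below the cutoff are removed: the result is 1 exactly where the
#' heatmap value is `>= cutoff`.
#'
#' @param heatmap Integer matrix in `[0, 255]`.
#' @param cutoff Integer in `[0, 255]`.
#' @return 0/1 integer matrix.
#' @export
apply_brightness_cutoff <- function(heatmap, cutoff) {
  check_scalar_num(cutoff, "cutoff", min = 0, max = 255)
  (heatmap >= cutoff) * 1L
}

#' Partition a binary map into connected components
#'
#' @param binary 0/1 matrix.
#' @param connectivity 8 (default) or 4.
#' @return List of pixel sets, each an n x 2 matrix of 0-based `(x, y)`
#'   coordinates, in scan order of first encounter.
#' @export
connected_components <- function(binary, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  labels <- cpp_label_components(matrix(as.integer(binary != 0),
                                        nrow(binary), ncol(binary)),
                                 as.integer(connectivity))
  n <- attr(labels, "n_labels")
  if (n == 0) return(list())
  idx <- which(labels > 0)
  lab <- labels[idx]
  ri <- (idx - 1) %% nrow(labels)       # 0-based row = y
  ci <- (idx - 1) %/% nrow(labels)      # 0-based col = x
  lapply(split(seq_along(idx), lab), function(k)
    cbind(x = ci[k], y = ri[k]))
}

#' Boundary polygon and Green's-theorem area of a pixel region
#'
#' Traces the outer boundary of a connected pixel set clockwise through the
#' centers of its boundary pixels (Moore-neighbor tracing with Jacob's
#' stopping criterion) and evaluates the enclosed area with the shoelace
#' formula. Because the polygon runs through pixel centers, the area is
#' typically slightly smaller than the literal pixel count: a solid
#' `w x h` rectangle gives `(w-1)(h-1)`, and single-pixel or 1-pixel-wide
#' regions give 0. Interior holes are ignored. Areas are in square microns
#' (1 px = 1 um).
#'
#' @param pixel_set n x 2 matrix of 0-based `(x, y)` pixel coordinates of
#'   one connected region.
#' @return `list(boundary_polygon, greens_area)`.
#' @export
region_area <- function(pixel_set) {
  pixel_set <- as.matrix(pixel_set)
  if (nrow(pixel_set) == 0) stop("empty pixel set")
  x0 <- min(pixel_set[, 1]); y0 <- min(pixel_set[, 2])
  w <- max(pixel_set[, 1]) - x0 + 1L
  h <- max(pixel_set[, 2]) - y0 + 1L
  local <- matrix(0L, h, w)
  local[cbind(pixel_set[, 2] - y0 + 1, pixel_set[, 1] - x0 + 1)] <- 1L
  poly <- cpp_trace_boundary(local, 1L)
  area <- cpp_polygon_area(poly)
  poly[, 1] <- poly[, 1] + x0
  poly[, 2] <- poly[, 2] + y0
  list(boundary_polygon = poly, greens_area = area)
}

#' Keep regions at or above an area cutoff
#'
#' @param regions List of detection regions (as inside an `mng_detections`
#'   object), each with a `greens_area` element.
#' @param cutoff_area Minimum Green's-theorem area retained (>= 0).
#' @return Filtered list.
#' @export
filter_regions <- function(regions, cutoff_area) {
  check_scalar_num(cutoff_area, "cutoff_area", min = 0)
  regions[vapply(regions, function(r) r$greens_area >= cutoff_area,
                 logical(1))]
}

#' Convert a heatmap into discrete MNG detections
#'
#' Composition of [apply_brightness_cutoff()], [connected_components()],
#' [region_area()] and [filter_regions()]: threshold the heatmap, split the
#' surviving pixels into connected regions, trace each region's boundary,
#' and keep regions whose Green's-theorem area is at least `cutoff_area`.
#' Centroids are unweighted means of member pixel coordinates.
#'
#' @param heatmap Integer matrix in `[0, 255]`.
#' @param cutoff_brightness Brightness cutoff in `[0, 255]`.
#' @param cutoff_area Area cutoff in square microns (>= 0).
#' @param connectivity Foreground connectivity, 8 (default) or 4.
#' @return An object of class `mng_detections`: list with `regions` (each
#'   region a list with `pixel_set`, `boundary_polygon`, `greens_area`,
#'   `centroid`), the cutoffs, and the heatmap provenance if present.
#' @export
detect <- function(heatmap, cutoff_brightness, cutoff_area,
                   connectivity = 8) {
  binary <- apply_brightness_cutoff(heatmap, cutoff_brightness)
  comps <- connected_components(binary, connectivity)
  regions <- lapply(comps, function(px) {
    ra <- region_area(px)
    list(pixel_set = px, boundary_polygon = ra$boundary_polygon,
         greens_area = ra$greens_area,
         centroid = c(x = mean(px[, 1]), y = mean(px[, 2])))
  })
  regions <- filter_regions(unname(regions), cutoff_area)
  structure(list(regions = regions,
                 cutoff_brightness = as.integer(cutoff_brightness),
                 cutoff_area = as.numeric(cutoff_area),
                 source_id = attr(heatmap, "source_id"),
                 checkpoint_epoch = attr(heatmap, "checkpoint_epoch")),
            class = "mng_detections")
}

#' @export
print.mng_detections <- function(x, ...) {
  cat(sprintf(
    "<mng_detections> %d region(s), brightness cutoff %d, area cutoff %.4g\n",
    length(x$regions), x$cutoff_brightness, x$cutoff_area))
  invisible(x)
}

#' @export
as.data.frame.mng_detections <- function(x, ...) {
  if (length(x$regions) == 0)
    return(data.frame(centroid_x = numeric(0), centroid_y = numeric(0),
                      greens_area = numeric(0), n_pixels = integer(0)))
  data.frame(
    centroid_x = vapply(x$regions, function(r) r$centroid[["x"]], 0),
    centroid_y = vapply(x$regions, function(r) r$centroid[["y"]], 0),
    greens_area = vapply(x$regions, function(r) r$greens_area, 0),
    n_pixels = vapply(x$regions, function(r) nrow(r$pixel_set), 0L))
}

#' Write detections to JSON / read them back
#'
#' The JSON layout is `{"cutoff_brightness", "cutoff_area", "regions":
#' [{"centroid": [x, y], "area": a, "polygon": [[x, y], ...]}]}`. Reading
#' reconstructs each region's pixel set by rasterizing its boundary
#' polygon, which recovers the member pixels of solid regions.
#'
#' @param detections An `mng_detections` object.
#' @param path File path.
#' @param shape `(height, width)` used by `read_detections` to rebuild
#'   pixel sets.
#' @return `path`, or the reconstructed `mng_detections`.
#' @export
write_detections <- function(detections, path) {
  obj <- list(cutoff_brightness = detections$cutoff_brightness,
              cutoff_area = detections$cutoff_area,
              regions = lapply(detections$regions, function(r)
                list(centroid = as.numeric(r$centroid),
                     area = r$greens_area,
                     polygon = lapply(seq_len(nrow(r$boundary_polygon)),
                                      function(i)
                                        as.numeric(r$boundary_polygon[i, ])))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path, shape) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  regions <- lapply(obj$regions, function(r) {
    poly <- do.call(rbind, lapply(r$polygon, as.numeric))
    px <- if (nrow(poly) >= 3) {
      m <- cpp_fill_polygon(poly, shape[1], shape[2])
      idx <- which(m == 1)
      cbind(x = (idx - 1) %/% nrow(m), y = (idx - 1) %% nrow(m))
    } else {
      cbind(x = round(poly[, 1]), y = round(poly[, 2]))
    }
    list(pixel_set = px, boundary_polygon = poly,
         greens_area = as.numeric(r$area),
         centroid = c(x = as.numeric(r$centroid[[1]]),
                      y = as.numeric(r$centroid[[2]])))
  })
  structure(list(regions = regions,
                 cutoff_brightness = as.integer(obj$cutoff_brightness),
                 cutoff_area = as.numeric(obj$cutoff_area),
                 source_id = NA_character_, checkpoint_epoch = NA_integer_),
            class = "mng_detections")
}
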