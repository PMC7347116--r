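# MNG annotations: construction, JSON serialization, rasterization.

#' Construct an MNG annotation
#'
#' One human-identified multinucleated germ cell: a center point plus a
#' filled polygon outlining the cell, in 0-based pixel coordinates
#' (x = column, y = row) on a given slide image.
#'
#' @param center Numeric length-2 vector `(x, y)`.
#' @param polygon Numeric n x 2 matrix of ordered vertices (n >= 3),
#'   columns `(x, y)`. Must be simple (non-self-intersecting).
#' @param slide_id,slice_id Identifiers of the image the annotation
#'   belongs to.
#' @return An object of class `mng_annotation`.
#' @export
mng_annotation <- function(center, polygon, slide_id = "slide",
                           slice_id = "slice") {
  center <- as.numeric(center)
  if (length(center) != 2 || anyNA(center))
    stop("`center` must be a numeric (x, y) pair")
  polygon <- as.matrix(polygon)
  if (!is.numeric(polygon) || ncol(polygon) != 2 || nrow(polygon) < 3 ||
      anyNA(polygon))
    stop("`polygon` must be a numeric matrix with >= 3 vertices")
  if (polygon_self_intersects(polygon))
    stop("`polygon` must be simple (non-self-intersecting)")
  if (!cpp_points_in_polygon(matrix(center, 1, 2), polygon))
    stop("`center` must lie inside or on the polygon")
  colnames(polygon) <- c("x", "y")
  structure(list(center = center, polygon = polygon,
                 slide_id = as.character(slide_id),
                 slice_id = as.character(slice_id)),
            class = "mng_annotation")
}

# O(n^2) segment-intersection test for polygon simplicity; adjacent edges
# share a vertex and are ignored. Annotation polygons are small, so this is
# never a bottleneck.
polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  seg <- function(i) rbind(poly[i, ], poly[i %% n + 1, ])
  cross2 <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  intersects <- function(p1, p2, p3, p4) {
    d1 <- cross2(p3, p4, p1); d2 <- cross2(p3, p4, p2)
    d3 <- cross2(p1, p2, p3); d4 <- cross2(p1, p2, p4)
    ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
  }
  if (n < 4) return(FALSE)
  for (i in seq_len(n - 2)) {
    for (j in seq(i + 2, n)) {
      if (i == 1 && j == n) next  # adjacent through closure
      si <- seg(i); sj <- seg(j)
      if (intersects(si[1, ], si[2, ], sj[1, ], sj[2, ])) return(TRUE)
    }
  }
  FALSE
}

#' Rasterize annotations to a filled truth mask
#'
#' Produces the binary training target: mask pixel = 1 exactly where the
#' pixel center lies inside (or on the boundary of) at least one annotation
#' polygon; overlapping polygons union. Inside/outside is decided by the
#' even-odd (ray casting) rule with boundary points counting as inside.
#'
#' @param annotations List of [mng_annotation()] objects (may be empty).
#' @param shape Integer `(height, width)` of the target mask.
#' @return A 0/1 integer matrix of dimension `shape`.
#' @export
rasterize_annotations <- function(annotations, shape) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2, all(shape >= 1))
  mask <- matrix(0L, shape[1], shape[2])
  for (a in annotations) {
    poly <- if (inherits(a, "mng_annotation")) a$polygon else as.matrix(a)
    if (nrow(poly) < 3) stop("polygon with < 3 vertices cannot be rasterized")
    mask <- mask | cpp_fill_polygon(poly, shape[1], shape[2])
  }
  mask * 1L
}

annotation_to_record <- function(a) {
  list(slide_id = a$slide_id, slice_id = a$slice_id,
       center = a$center,
       polygon = lapply(seq_len(nrow(a$polygon)),
                        function(i) as.numeric(a$polygon[i, ])))
}

#' Write annotations to a JSON file
#'
#' The file holds a list of objects
#' `{"slide_id", "slice_id", "center": [x, y], "polygon": [[x, y], ...]}`.
#' Writing then reading a set of annotations is lossless.
#'
#' @param annotations List of [mng_annotation()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  records <- lapply(annotations, annotation_to_record)
  jsonlite::write_json(records, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read annotations from a JSON file
#'
#' @param path Path to a JSON annotation file as written by
#'   [write_annotations()].
#' @return A list of [mng_annotation()] objects.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  records <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("cannot parse annotation file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  lapply(seq_along(records), function(i) {
    r <- records[[i]]
    need <- c("slide_id", "slice_id", "center", "polygon")
    if (!all(need %in% names(r)))
      stop(sprintf("annotation record %d in '%s' is missing fields: %s",
                   i, path, paste(setdiff(need, names(r)), collapse = ", ")),
           call. = FALSE)
    poly <- do.call(rbind, lapply(r$polygon, as.numeric))
    if (is.null(poly) || nrow(poly) < 3)
      stop(sprintf("annotation record %d in '%s' has a polygon with < 3 vertices",
                   i, path), call. = FALSE)
    mng_annotation(as.numeric(unlist(r$center)), poly,
                   slide_id = r$slide_id, slice_id = r$slice_id)
  })
}
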