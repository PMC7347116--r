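# Object-level evaluation: detection/annotation matching, confusion
# counts, precision/recall/F1, FP:FN ratios, cross-fold aggregates.

#' Confusion counts
#'
#' @param tp,fp,fn Non-negative integers. `tp + fn` equals the number of
#'   reference MNGs and `tp + fp` the number of detections.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, fn) {
  check_scalar_num(tp, "tp", min = 0)
  check_scalar_num(fp, "fp", min = 0)
  check_scalar_num(fn, "fn", min = 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp %d, fp %d, fn %d\n", x$tp, x$fp, x$fn))
  invisible(x)
}

#' Add two sets of confusion counts (pooling across images)
#' @param e1,e2 `confusion_counts`.
#' @return Pooled `confusion_counts`.
#' @export
`+.confusion_counts` <- function(e1, e2) {
  confusion_counts(e1$tp + e2$tp, e1$fp + e2$fp, e1$fn + e2$fn)
}

#' Match detections to reference annotations
#'
#' One-to-one greedy matching: a (detection, annotation) pair is a
#' candidate when the detection's pixel set overlaps the annotation's
#' filled polygon by at least `min_overlap` pixels, or the detection
#' centroid lies inside the polygon. Candidates are accepted in descending
#' pixel-overlap order (ties broken by detection then annotation order);
#' each detection and each annotation matches at most once. A detection
#' covering two annotations therefore counts as one true positive plus one
#' false negative.
#'
#' @param detections An `mng_detections` object (see [detect()]).
#' @param annotations List of [mng_annotation()] on the same image.
#' @param shape `(height, width)` of the image.
#' @param min_overlap Minimum overlapping pixel count for the overlap rule
#'   (default 1).
#' @return A `confusion_counts` with attribute `matches`, a data.frame of
#'   accepted (detection, annotation, overlap) triples.
#' @export
match_detections <- function(detections, annotations, shape,
                             min_overlap = 1) {
  stopifnot(inherits(detections, "mng_detections"))
  if (length(annotations) > 0 && !is.null(detections$source_id) &&
      !is.na(detections$source_id)) {
    ann_ids <- vapply(annotations, function(a)
      paste(a$slide_id, a$slice_id, sep = "/"), "")
    if (!all(ann_ids == detections$source_id))
      stop("detections and annotations refer to different images")
  }
  nd <- length(detections$regions)
  na <- length(annotations)
  if (na == 0 || nd == 0) {
    cc <- confusion_counts(0, nd, na)
    attr(cc, "matches") <- data.frame(detection = integer(0),
                                      annotation = integer(0),
                                      overlap = numeric(0))
    return(cc)
  }
  H <- shape[1]; W <- shape[2]
  ann_lin <- lapply(annotations, function(a) {
    m <- cpp_fill_polygon(a$polygon, H, W)
    which(m == 1)
  })
  cand <- list()
  for (i in seq_len(nd)) {
    r <- detections$regions[[i]]
    det_lin <- r$pixel_set[, 2] + 1 + r$pixel_set[, 1] * H
    for (j in seq_len(na)) {
      ov <- sum(det_lin %in% ann_lin[[j]])
      cin <- as.logical(cpp_points_in_polygon(
        matrix(r$centroid, 1, 2), annotations[[j]]$polygon))
      if (ov >= min_overlap || cin)
        cand[[length(cand) + 1]] <- c(i, j, ov)
    }
  }
  used_d <- logical(nd); used_a <- logical(na)
  matches <- data.frame(detection = integer(0), annotation = integer(0),
                        overlap = numeric(0))
  if (length(cand) > 0) {
    cm <- do.call(rbind, cand)
    ord <- order(-cm[, 3], cm[, 1], cm[, 2])
    for (k in ord) {
      i <- cm[k, 1]; j <- cm[k, 2]
      if (!used_d[i] && !used_a[j]) {
        used_d[i] <- TRUE; used_a[j] <- TRUE
        matches <- rbind(matches,
                         data.frame(detection = i, annotation = j,
                                    overlap = cm[k, 3]))
      }
    }
  }
  tp <- sum(used_d)
  cc <- confusion_counts(tp, nd - tp, na - tp)
  attr(cc, "matches") <- matches
  cc
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`, and F1 is their
#' harmonic mean `2 p r / (p + r)`. When `tp = 0` but `fp + fn > 0`, the F1
#' is 0; when all three counts are 0 the metrics are undefined and an error
#' is signalled.
#'
#' @param counts A `confusion_counts`.
#' @return An object of class `evaluation_result` with elements
#'   `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  if (tp + fp + fn == 0)
    stop("precision/recall/F1 are undefined when tp = fp = fn = 0")
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  structure(list(precision = p, recall = r, f1 = f1),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> precision %.3f, recall %.3f, F1 %.3f\n",
              x$precision, x$recall, x$f1))
  invisible(x)
}

#' False-positive to false-negative ratio
#'
#' @param counts A `confusion_counts` with `fn > 0`.
#' @return `fp / fn`.
#' @export
fp_fn_ratio <- function(counts) {
  if (counts$fn == 0)
    stop("FP:FN ratio is undefined when fn = 0")
  counts$fp / counts$fn
}

#' Mean and sample standard deviation of a vector of scores
#'
#' @param values Nonempty numeric vector.
#' @return `list(mean, sd)`; `sd` (computed with the n-1 denominator) is
#'   `NA` for a single value.
#' @export
aggregate_scores <- function(values) {
  if (length(values) == 0) stop("cannot aggregate an empty vector")
  list(mean = mean(values),
       sd = if (length(values) >= 2) sd(values) else NA_real_)
}

#' Flat evaluation table for a set of images
#'
#' One row per image: confusion counts and derived metrics, ready to be
#' written as the evaluation report CSV.
#'
#' @param counts_list List of `confusion_counts`, one per image.
#' @param ids Optional character vector of image identifiers.
#' @return A data.frame with columns `id, tp, fp, fn, precision, recall,
#'   f1`.
#' @export
evaluation_table <- function(counts_list, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("image_%03d", seq_along(counts_list))
  rows <- lapply(seq_along(counts_list), function(i) {
    cc <- counts_list[[i]]
    er <- precision_recall_f1(cc)
    data.frame(id = ids[i], tp = cc$tp, fp = cc$fp, fn = cc$fn,
               precision = er$precision, recall = er$recall, f1 = er$f1)
  })
  do.call(rbind, rows)
}
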