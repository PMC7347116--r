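# Batch-stratified cross-validation and grid search over
# (epoch, cutoff brightness, cutoff area).

#' Batch-stratified fold assignment
#'
#' Slides are sorted by MNG count (descending) and chunked into consecutive
#' groups of `n_folds` (the final group may be smaller). Within each group,
#' slides go to distinct folds, so no fold receives two slides from the
#' same group; among all such assignments the one minimizing the variance
#' of per-fold MNG totals is selected. With at most 6 groups the search is
#' exhaustive (depth-first over per-group permutations with a water-filling
#' lower bound for pruning); with more groups it is sequential-greedy,
#' choosing for each group in order the permutation that minimizes the
#' running variance.
#'
#' @param slide_mng_counts Named numeric vector: MNG count per slide.
#' @param n_folds Number of folds (default 5).
#' @return An object of class `fold_assignment`: list with `table`
#'   (data.frame slide/count/group/fold, folds 0-based), `fold_totals`,
#'   `n_folds`.
#' @export
stratify_slides <- function(slide_mng_counts, n_folds = 5) {
  n_folds <- as.integer(n_folds)
  if (length(slide_mng_counts) < n_folds)
    stop("need at least as many slides as folds")
  if (is.null(names(slide_mng_counts)))
    names(slide_mng_counts) <- sprintf("slide_%02d",
                                       seq_along(slide_mng_counts))
  ord <- order(-slide_mng_counts)
  counts <- slide_mng_counts[ord]
  n <- length(counts)
  groups <- split(seq_len(n), ceiling(seq_len(n) / n_folds))
  ngrp <- length(groups)

  perms_of <- function(g) {
    # all injective maps of a size-g group onto distinct folds
    if (g == n_folds) all_permutations(n_folds)
    else {
      combos <- utils::combn(n_folds, g, simplify = FALSE)
      do.call(rbind, lapply(combos, function(cb) {
        p <- all_permutations(g)
        matrix(cb[p], nrow(p), g)
      }))
    }
  }
  group_perms <- lapply(groups, function(ix) perms_of(length(ix)))

  best <- NULL
  best_ss <- Inf
  nodes <- 0
  # Lower bound on the final sum of squares: water-fill the remaining mass
  # onto the current totals as evenly as possible (continuous relaxation).
  lower_bound <- function(totals, remaining) {
    ts <- sort(totals)
    cum <- cumsum(ts)
    for (k in seq_len(n_folds)) {
      L <- (cum[k] + remaining) / k
      if (k == n_folds || L <= ts[k + 1]) {
        if (k == n_folds) return(k * L^2)
        return(k * L^2 + sum(ts[(k + 1):n_folds]^2))
      }
    }
    sum(ts^2)
  }
  assign_rec <- function(gi, totals, assignment) {
    if (nodes > 2e6) return(invisible())  # safety cap; keeps best so far
    if (gi > ngrp) {
      ss <- sum(totals^2)
      if (ss < best_ss) {
        best_ss <<- ss
        best <<- assignment
      }
      return(invisible())
    }
    remaining <- sum(counts[unlist(groups[gi:ngrp])])
    if (lower_bound(totals, remaining) > best_ss + 1e-9) return(invisible())
    ix <- groups[[gi]]
    pm <- group_perms[[gi]]
    for (r in seq_len(nrow(pm))) {
      nodes <<- nodes + 1
      t2 <- totals
      t2[pm[r, ]] <- t2[pm[r, ]] + counts[ix]
      a2 <- assignment
      a2[ix] <- pm[r, ]
      assign_rec(gi + 1, t2, a2)
    }
    invisible()
  }
  greedy_assign <- function() {
    totals <- rep(0, n_folds)
    assignment <- rep(NA_integer_, n)
    for (gi in seq_len(ngrp)) {
      ix <- groups[[gi]]
      pm <- group_perms[[gi]]
      ss <- apply(pm, 1, function(p) {
        t2 <- totals
        t2[p] <- t2[p] + counts[ix]
        var(t2)
      })
      rbest <- which.min(ss)
      assignment[ix] <- pm[rbest, ]
      totals[pm[rbest, ]] <- totals[pm[rbest, ]] + counts[ix]
    }
    assignment
  }
  assignment <- if (ngrp <= 6) {
    assign_rec(1, rep(0, n_folds), rep(NA_integer_, n))
    if (is.null(best)) greedy_assign() else best
  } else greedy_assign()

  tab <- data.frame(slide = names(counts), count = as.numeric(counts),
                    group = rep(seq_len(ngrp),
                                vapply(groups, length, 0L)),
                    fold = assignment - 1L, stringsAsFactors = FALSE)
  totals <- vapply(seq_len(n_folds) - 1L,
                   function(f) sum(tab$count[tab$fold == f]), 0)
  structure(list(table = tab, fold_totals = totals, n_folds = n_folds),
            class = "fold_assignment")
}

all_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(first) {
    rest <- seq_len(k)[-first]
    cbind(first, matrix(rest[sub], nrow(sub), k - 1))
  }))
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("<fold_assignment> %d slides into %d folds; totals: %s\n",
              nrow(x$table), x$n_folds,
              paste(x$fold_totals, collapse = ", ")))
  invisible(x)
}

#' Train/test/holdout fold configurations
#'
#' With folds numbered `0 .. n_folds-1`, each fold serves once as the
#' holdout set; the test set is the fold numerically after the holdout
#' fold (wrapping back to fold 0), and the remaining folds train.
#'
#' @param n_folds Number of folds (>= 3).
#' @return List of `list(train, test, holdout)` (0-based fold ids).
#' @export
fold_configurations <- function(n_folds = 5) {
  if (n_folds < 3) stop("need at least 3 folds for train/test/holdout")
  lapply(seq_len(n_folds) - 1L, function(h) {
    t <- (h + 1L) %% n_folds
    list(train = setdiff(seq_len(n_folds) - 1L, c(h, t)),
         test = t, holdout = h)
  })
}

#' Select the optimal grid point
#'
#' Picks the row maximizing F1 with deterministic tie-breaking: lowest
#' epoch first (cheapest model), then highest brightness, then highest
#' area (most conservative detector).
#'
#' @param grid data.frame with columns `epoch`, `brightness`, `area`, `f1`.
#' @return The index of the selected row.
#' @export
select_optimal <- function(grid) {
  stopifnot(all(c("epoch", "brightness", "area", "f1") %in% names(grid)))
  ord <- order(-grid$f1, grid$epoch, -grid$brightness, -grid$area)
  ord[1]
}

#' Grid search over epoch, brightness cutoff and area cutoff
#'
#' For every combination, predicts heatmaps with the epoch's checkpoint,
#' runs detection with the cutoffs, matches against annotations, pools the
#' confusion counts over all test images, and computes F1. The maximizing
#' combination is selected with the [select_optimal()] tie-break.
#'
#' @param checkpoints List of `unet_checkpoint` (epochs 1..E).
#' @param images List of [slide_image()] forming the test set.
#' @param annotations List (parallel to `images`) of annotation lists.
#' @param brightness_grid Integer vector of brightness cutoffs.
#' @param area_grid Numeric vector of area cutoffs.
#' @param panel_size,stride Tiling parameters for prediction (defaults:
#'   training input size, half overlap).
#' @param connectivity Foreground connectivity for detection.
#' @return Object of class `grid_search_result`: `grid` (full data.frame of
#'   epoch/brightness/area/tp/fp/fn/f1), `optimal` (selected row as a
#'   list), `test_counts` (`confusion_counts` at the optimum).
#' @export
grid_search <- function(checkpoints, images, annotations,
                        brightness_grid, area_grid,
                        panel_size = NULL, stride = NULL,
                        connectivity = 8) {
  if (length(images) == 0) stop("empty test set")
  if (length(brightness_grid) == 0 || length(area_grid) == 0)
    stop("empty parameter grid")
  panel_size <- panel_size %||% checkpoints[[1]]$config$input_size
  stride <- stride %||% (panel_size / 2)
  shapes <- lapply(images, dim)
  rows <- list()
  for (ck in checkpoints) {
    heats <- lapply(images, function(im)
      predict_heatmap(ck, im, panel_size, stride))
    for (b in brightness_grid) {
      # detection at the smallest area cutoff, then filtered upward: the
      # region list only shrinks as the cutoff grows
      base <- lapply(seq_along(heats), function(i)
        detect(heats[[i]], b, min(area_grid), connectivity))
      for (a in area_grid) {
        cc <- confusion_counts(0, 0, 0)
        for (i in seq_along(images)) {
          d <- base[[i]]
          d$regions <- filter_regions(d$regions, a)
          d$cutoff_area <- a
          cc <- cc + match_detections(d, annotations[[i]], shapes[[i]])
        }
        er <- tryCatch(precision_recall_f1(cc),
                       error = function(e) list(f1 = NA_real_))
        rows[[length(rows) + 1]] <-
          data.frame(epoch = ck$epoch, brightness = b, area = a,
                     tp = cc$tp, fp = cc$fp, fn = cc$fn, f1 = er$f1)
      }
    }
  }
  grid <- do.call(rbind, rows)
  grid$f1[is.na(grid$f1)] <- 0
  k <- select_optimal(grid)
  structure(list(grid = grid, optimal = as.list(grid[k, ]),
                 test_counts = confusion_counts(grid$tp[k], grid$fp[k],
                                                grid$fn[k])),
            class = "grid_search_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.grid_search_result <- function(x, ...) {
  o <- x$optimal
  cat(sprintf(
    "<grid_search_result> %d grid points; optimum: epoch %d, brightness %d, area %.4g (test F1 %.3f)\n",
    nrow(x$grid), o$epoch, o$brightness, o$area, o$f1))
  invisible(x)
}

#' Evaluate the selected model on the holdout set
#'
#' Applies the optimal (epoch, brightness, area) combination unchanged to
#' the holdout images and reports pooled confusion counts and F1. The
#' holdout set plays no role in selection.
#'
#' @param result A `grid_search_result`.
#' @param checkpoints The checkpoint list used for the search.
#' @param images,annotations Holdout images and their annotation lists.
#' @param panel_size,stride,connectivity As in [grid_search()].
#' @return List with `counts` (`confusion_counts`), `precision`, `recall`,
#'   `f1`.
#' @export
evaluate_holdout <- function(result, checkpoints, images, annotations,
                             panel_size = NULL, stride = NULL,
                             connectivity = 8) {
  stopifnot(inherits(result, "grid_search_result"))
  epochs <- vapply(checkpoints, function(c) c$epoch, 0L)
  idx <- match(result$optimal$epoch, epochs)
  if (is.na(idx)) stop("optimal epoch checkpoint not available")
  ck <- checkpoints[[idx]]
  panel_size <- panel_size %||% ck$config$input_size
  stride <- stride %||% (panel_size / 2)
  cc <- confusion_counts(0, 0, 0)
  for (i in seq_along(images)) {
    h <- predict_heatmap(ck, images[[i]], panel_size, stride)
    d <- detect(h, result$optimal$brightness, result$optimal$area,
                connectivity)
    cc <- cc + match_detections(d, annotations[[i]], dim(images[[i]]))
  }
  er <- precision_recall_f1(cc)
  list(counts = cc, precision = er$precision, recall = er$recall,
       f1 = er$f1)
}

#' Run the full batch-stratified cross-validation protocol
#'
#' Stratifies the scenes into folds by MNG count, and for each of the
#' `n_folds` fold configurations trains a fresh network on the training
#' folds' augmented panels, selects (epoch, brightness, area) by grid
#' search on the test fold, and measures final accuracy on the holdout
#' fold.
#'
#' @param scenes List of `mng_scene` objects (see [generate_scene()]), or
#'   equivalent lists with `image`, `annotations`, `mask`.
#' @param net_config [network_config()] for training.
#' @param aug_config [augmentation_config()] for panel sampling; sampled
#'   panels are always dihedral-expanded.
#' @param brightness_grid,area_grid Cutoff grids for the search.
#' @param n_folds Number of folds (default 5).
#' @param stride Inference stride (default `panel_size / 2`).
#' @param seed Global seed; per-configuration training seeds derive from
#'   it.
#' @return Object of class `crossval_result`: `summary` (one row per fold
#'   configuration, mirroring the grid-search report columns),
#'   `assignment`, `holdout_mean`, `holdout_sd`, and per-configuration
#'   `details`.
#' @export
run_crossval <- function(scenes, net_config, aug_config,
                         brightness_grid = seq(100L, 254L, by = 2L),
                         area_grid = c(10, 20, 50, 100, 150, 200, 300,
                                       400, 500, 700, 1000),
                         n_folds = 5, stride = NULL, seed = 1L) {
  counts <- vapply(scenes, function(s) length(s$annotations), 0)
  names(counts) <- vapply(scenes, function(s) s$image$slide_id, "")
  assignment <- stratify_slides(counts, n_folds)
  fold_of <- setNames(assignment$table$fold, assignment$table$slide)
  configs <- fold_configurations(n_folds)
  details <- list()
  rows <- list()
  for (cf in configs) {
    train_scenes <- scenes[fold_of[names(counts)] %in% cf$train]
    test_ix <- which(fold_of[names(counts)] == cf$test)
    hold_ix <- which(fold_of[names(counts)] == cf$holdout)
    panels <- list()
    for (s in train_scenes) {
      ac <- aug_config
      ac$seed <- stage_seed(seed + cf$holdout, paste0("panels_",
                                                      s$image$slide_id))
      base <- sample_mng_panels(s$image, s$mask, s$annotations, ac)
      for (p in base) panels <- c(panels, dihedral_expand(p))
    }
    if (length(panels) == 0)
      stop("no MNG panels available in the training folds")
    nc <- net_config
    nc$seed <- stage_seed(seed + cf$holdout, "train")
    model <- build_unet(nc)
    checkpoints <- train_unet(model, panels, nc)
    gs <- grid_search(checkpoints,
                      lapply(scenes[test_ix], `[[`, "image"),
                      lapply(scenes[test_ix], `[[`, "annotations"),
                      brightness_grid, area_grid, stride = stride)
    ho <- evaluate_holdout(gs, checkpoints,
                           lapply(scenes[hold_ix], `[[`, "image"),
                           lapply(scenes[hold_ix], `[[`, "annotations"),
                           stride = stride)
    test_f1 <- precision_recall_f1(gs$test_counts)$f1
    rows[[length(rows) + 1]] <- data.frame(
      holdout_fold = cf$holdout, test_fold = cf$test,
      optimal_epoch = gs$optimal$epoch,
      optimal_brightness = gs$optimal$brightness,
      optimal_area = gs$optimal$area,
      test_tp = gs$test_counts$tp, test_fp = gs$test_counts$fp,
      test_fn = gs$test_counts$fn, test_f1 = test_f1,
      holdout_tp = ho$counts$tp, holdout_fp = ho$counts$fp,
      holdout_fn = ho$counts$fn, holdout_f1 = ho$f1)
    details[[length(details) + 1]] <- list(config = cf, grid_search = gs,
                                           holdout = ho)
  }
  summary <- do.call(rbind, rows)
  agg <- aggregate_scores(summary$holdout_f1)
  structure(list(summary = summary, assignment = assignment,
                 holdout_mean = agg$mean, holdout_sd = agg$sd,
                 details = details),
            class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat("<crossval_result>\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("mean holdout F1 %.3f (sd %s)\n", x$holdout_mean,
              ifelse(is.na(x$holdout_sd), "NA",
                     sprintf("%.3f", x$holdout_sd))))
  invisible(x)
}
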