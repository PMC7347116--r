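# Reference confusion counts from the published five-fold evaluation of
# this pipeline on rat fetal-testis slides, plus the two human test
# scorers measured against the human reference scorer. These counts are
# inputs for recomputing the published accuracy statistics (F1 scores,
# cross-fold mean/sd, FP:FN ratios) with the package's own evaluation
# functions.

#' Reference confusion counts for the rat-testis MNG benchmark
#'
#' Returns per-fold test-set and holdout-set confusion counts (and the
#' selected grid-search parameters) from the published five-fold
#' evaluation of this detection protocol, together with the confusion
#' counts of two human test scorers measured against the reference human
#' scorer. `printed_f1` is the F1 value as printed in the published
#' tables, at 3 decimals; all statistics can be recomputed from the raw
#' counts via [precision_recall_f1()], [fp_fn_ratio()] and
#' [aggregate_scores()]. In the holdout table, fold 3 is the
#' best-performing configuration.
#'
#' @param group Optional filter: `"test"`, `"holdout"` or `"human"`.
#' @return A data.frame with columns `group, label, holdout_fold,
#'   test_fold, optimal_epoch, optimal_brightness, optimal_area, tp, fp,
#'   fn, printed_f1`.
#' @export
reference_counts <- function(group = NULL) {
  path <- system.file("extdata", "reference_counts.csv",
                      package = "mngdetect", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(group)) df <- df[df$group %in% group, , drop = FALSE]
  rownames(df) <- NULL
  df
}
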