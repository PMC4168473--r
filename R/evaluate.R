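#' Build an evaluation result from confusion counts
#'
#' @param tp,tn,fp,fn confusion-matrix counts.
#' @return object of class `eval_result`: the counts plus
#'   `sensitivity = tp/(tp+fn)`, `specificity = tn/(tn+fp)` and
#'   `accuracy = (tp+tn)/total`.
#' @export
eval_result <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  total <- tp + tn + fp + fn
  out <- list(
    tp = tp, tn = tn, fp = fp, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = if (total > 0) (tp + tn) / total else NA_real_)
  class(out) <- "eval_result"
  out
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "eval_result: sens %.1f%%  spec %.1f%%  acc %.1f%%  (tp %d fn %d tn %d fp %d)\n",
    100 * x$sensitivity, 100 * x$specificity, 100 * x$accuracy,
    x$tp, x$fn, x$tn, x$fp))
  invisible(x)
}

#' Evaluate predictions against truth
#'
#' @param predictions,truth equal-length label vectors; `NA` predictions
#'   (e.g. skipped folds) are dropped with a warning.
#' @param positive the positive-class label (sensitivity numerator).
#' @return an [eval_result()].
#' @export
evaluate <- function(predictions, truth, positive) {
  if (length(predictions) != length(truth))
    stop("predictions and truth differ in length")
  keep <- !is.na(predictions)
  if (!all(keep)) {
    warning(sum(!keep), " prediction(s) missing; dropped from evaluation")
    predictions <- predictions[keep]; truth <- truth[keep]
  }
  labs <- unique(truth)
  if (!positive %in% labs)
    stop("positive class '", positive, "' absent from truth labels")
  if (!all(predictions %in% labs))
    stop("prediction contains label unseen in truth")
  pos_t <- truth == positive
  pos_p <- predictions == positive
  eval_result(tp = sum(pos_t & pos_p), tn = sum(!pos_t & !pos_p),
              fp = sum(!pos_t & pos_p), fn = sum(pos_t & !pos_p))
}

#' Cross-validation fold assignment
#'
#' @param labels class labels (defines stratification and n).
#' @param scheme `"loocv"` or `"stratified"` k-fold.
#' @param k folds for the stratified scheme.
#' @param seed seed for the stratified shuffle.
#' @return integer fold id per sample.
#' @export
make_folds <- function(labels, scheme = c("loocv", "stratified"), k = 5L,
                       seed = 1L) {
  scheme <- match.arg(scheme)
  n <- length(labels)
  if (scheme == "loocv") return(seq_len(n))
  if (k < 2L || k > n) stop_field("k", "must be in [2, n]")
  fold <- integer(n)
  with_seed(seed, {
    for (g in unique(labels)) {
      ii <- which(labels == g)
      fold[ii] <- rep_len(seq_len(k), length(ii))[sample(length(ii))]
    }
  })
  fold
}
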