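# R-side wrappers around the compiled SMO solver. The RBF kernel follows
# the sigma convention K(x, y) = exp(-||x - y||^2 / (2 sigma^2)); callers
# using gamma = 1/(2 sigma^2) must convert at the interface.

labels_to_pm1 <- function(y, positive) {
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2L) stop("need exactly 2 classes")
  if (is.null(positive)) positive <- classes[2]
  if (!positive %in% classes) stop("positive class absent from labels")
  list(y = ifelse(y == positive, 1L, -1L), positive = positive,
       negative = setdiff(classes, positive))
}

pm1_to_labels <- function(p, enc) {
  out <- rep(NA_character_, length(p))
  out[p == 1L] <- enc$positive
  out[p == -1L] <- enc$negative
  out
}

# per-feature squared-difference cube (n x n x F), features in column order
distance_cube <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); F <- ncol(x)
  cube <- array(0, dim = c(n, n, F))
  for (f in seq_len(F)) {
    d <- outer(x[, f], x[, f], "-")
    cube[, , f] <- d * d
  }
  dimnames(cube) <- list(NULL, NULL, colnames(x))
  cube
}

#' Cross-validated RBF-SVM predictions
#'
#' @param x samples x features matrix (already standardized if desired).
#' @param y two-class labels.
#' @param C box constraint.
#' @param sigma RBF width, `K = exp(-d^2 / (2 sigma^2))`.
#' @param folds fold ids (default leave-one-out). Single-class training
#'   folds are skipped with a warning (NA predictions).
#' @param positive positive-class label.
#' @return list: `result` ([eval_result()]), `predictions`.
#' @export
svm_classify <- function(x, y, C, sigma, folds = NULL, positive = NULL) {
  enc <- labels_to_pm1(y, positive)
  if (is.null(folds)) folds <- make_folds(y, "loocv")
  D <- as.matrix(dist(zscore_noop(x)))^2
  p <- .cpp_svm_cv_predict(D, enc$y, C, sigma, as.integer(folds))
  if (any(p == 0L))
    warning(sum(p == 0L), " sample(s) in skipped single-class folds")
  pred <- pm1_to_labels(p, enc)
  list(result = evaluate(pred, as.character(y), enc$positive),
       predictions = pred)
}

zscore_noop <- function(x) as.matrix(x)  # standardization decided by caller

# CV accuracy of the RBF-SVM on an ordered feature subset, with the kernel
# assembled exactly as the greedy selector assembles it (product of
# per-feature factors, in order). Used by brute-force oracles that must
# reproduce greedy results bit-exactly.
svm_subset_cv_accuracy <- function(x, y, cols, C, sigma, folds = NULL,
                                   positive = NULL) {
  enc <- labels_to_pm1(y, positive)
  if (is.null(folds)) folds <- make_folds(y, "loocv")
  n <- nrow(x)
  inv2s2 <- 1 / (2 * sigma * sigma)
  K <- matrix(1, n, n)
  for (j in cols) {
    d <- outer(x[, j], x[, j], "-")
    K <- K * exp(-(d * d) * inv2s2)
  }
  p <- .cpp_svm_cv_predict_K(K, enc$y, C, as.integer(folds))
  ok <- p != 0L
  if (any(ok)) mean(p[ok] == enc$y[ok]) else 0
}

#' Grid search for the SVM box constraint and kernel width
#'
#' Maximizes cross-validated accuracy over the `C_grid` x `sigma_grid`
#' lattice on the full candidate feature set; ties are broken by the
#' smaller `C`, then the smaller `sigma`.
#'
#' @inheritParams svm_classify
#' @param C_grid,sigma_grid strictly positive candidate values.
#' @return list: `C`, `sigma`, `cv_accuracy`, `grid` (data.frame of all
#'   combinations and their accuracies).
#' @export
svm_grid_search <- function(x, y, C_grid = default_C_grid(),
                            sigma_grid = default_sigma_grid(),
                            folds = NULL, positive = NULL) {
  if (!length(C_grid) || any(C_grid <= 0))
    stop_field("C_grid", "must be non-empty and strictly positive")
  if (!length(sigma_grid) || any(sigma_grid <= 0))
    stop_field("sigma_grid", "must be non-empty and strictly positive")
  enc <- labels_to_pm1(y, positive)
  if (is.null(folds)) folds <- make_folds(y, "loocv")
  D <- as.matrix(dist(as.matrix(x)))^2
  res <- expand.grid(C = sort(C_grid), sigma = sort(sigma_grid))
  res$accuracy <- NA_real_
  for (i in seq_len(nrow(res))) {
    p <- .cpp_svm_cv_predict(D, enc$y, res$C[i], res$sigma[i],
                             as.integer(folds))
    ok <- p != 0L
    res$accuracy[i] <- if (any(ok)) mean(p[ok] == enc$y[ok]) else 0
  }
  # ties: smaller C, then smaller sigma (grid sorted C-major)
  ord <- order(-res$accuracy, res$C, res$sigma)
  best <- res[ord[1], ]
  list(C = best$C, sigma = best$sigma, cv_accuracy = best$accuracy,
       grid = res)
}

#' @rdname svm_grid_search
#' @export
default_C_grid <- function() 10^seq(0, 3, length.out = 7)

#' @rdname svm_grid_search
#' @export
default_sigma_grid <- function() c(0.1, 0.2, 0.5, 1, 2, 5, 10, 20, 50)

#' Greedy forward index selection for the SVM
#'
#' At step k, adds the candidate index maximizing cross-validated accuracy
#' of the SVM on the current set plus that candidate (ties: lexicographically
#' smallest index name), recording cumulative sensitivity, specificity and
#' accuracy per step. Stops after `max_indices` steps.
#'
#' @inheritParams svm_classify
#' @param max_indices selection budget (default 10).
#' @return object of class `selection_trace`: data.frame with `step`,
#'   `index_name`, `tp`, `fn`, `tn`, `fp`, `sensitivity`, `specificity`,
#'   `accuracy`; attributes `C`, `sigma`.
#' @export
greedy_svm_selection <- function(x, y, C, sigma, max_indices = 10L,
                                 folds = NULL, positive = NULL) {
  x <- as.matrix(x)
  if (ncol(x) < 1L) stop("need at least one candidate index")
  enc <- labels_to_pm1(y, positive)
  if (is.null(folds)) folds <- make_folds(y, "loocv")
  ord_cols <- order(colnames(x))        # lexicographic tie-break
  x <- x[, ord_cols, drop = FALSE]
  cube <- distance_cube(x)
  res <- .cpp_svm_greedy_select(cube, enc$y, C, sigma,
                                as.integer(max_indices),
                                as.integer(folds))
  steps <- which(res$order > 0L)
  rows <- lapply(steps, function(s) {
    pred <- pm1_to_labels(res$preds[s, ], enc)
    er <- evaluate(pred, as.character(y), enc$positive)
    data.frame(step = s, index_name = colnames(x)[res$order[s]],
               tp = er$tp, fn = er$fn, tn = er$tn, fp = er$fp,
               sensitivity = er$sensitivity, specificity = er$specificity,
               accuracy = er$accuracy)
  })
  trace <- do.call(rbind, rows)
  attr(trace, "C") <- C
  attr(trace, "sigma") <- sigma
  class(trace) <- c("selection_trace", "data.frame")
  trace
}
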