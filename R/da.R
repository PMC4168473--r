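# Gaussian discriminant analysis (linear and quadratic), implemented
# directly so singular within-class covariances fall back to a logged ridge
# shrinkage instead of an error.

ridge_until_ok <- function(S, label) {
  lam <- 0
  d <- nrow(S)
  scale <- mean(diag(S))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  for (try in 0:8) {
    Sr <- S + diag(lam * scale, d)
    ok <- tryCatch({
      ch <- chol(Sr)
      rc <- min(diag(ch))^2 / max(diag(ch))^2
      rc > 1e-12
    }, error = function(e) FALSE)
    if (ok) {
      if (lam > 0)
        message(sprintf(
          "%s covariance singular; ridge shrinkage lambda = %.1e applied",
          label, lam))
      return(S + diag(lam * scale, d))
    }
    lam <- if (lam == 0) 1e-8 else lam * 100
  }
  stop(label, " covariance irreparably singular")
}

#' Fit a linear or quadratic discriminant classifier
#'
#' LDA uses the pooled covariance, QDA a covariance per class; both use
#' training-set class priors. A singular covariance triggers a logged ridge
#' fallback (`S + lambda * mean(diag(S)) * I`).
#'
#' @param x numeric matrix (samples x variables).
#' @param y two-level factor/character labels.
#' @param kind `"linear"` or `"quadratic"`.
#' @return object of class `da_model`.
#' @export
da_fit <- function(x, y, kind = c("linear", "quadratic")) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2L) stop("da_fit needs exactly 2 classes in training data")
  mu <- lapply(classes, function(g) colMeans(x[y == g, , drop = FALSE]))
  nk <- vapply(classes, function(g) sum(y == g), numeric(1))
  if (any(nk < 2)) stop("each class needs >= 2 training samples")
  covs <- lapply(classes, function(g) cov(x[y == g, , drop = FALSE]))
  if (kind == "linear") {
    pooled <- Reduce(`+`, Map(function(S, n) (n - 1) * S, covs, nk)) /
      (sum(nk) - 2)
    pooled <- ridge_until_ok(pooled, "pooled")
    covs <- list(pooled, pooled)
  } else {
    covs <- Map(function(S, g) ridge_until_ok(S, paste("class", g)),
                covs, classes)
  }
  structure(list(classes = classes, mu = mu, covs = covs,
                 prior = nk / sum(nk), kind = kind),
            class = "da_model")
}

#' @rdname da_fit
#' @param object fitted `da_model`.
#' @param newdata matrix of samples to classify.
#' @param ... unused.
#' @export
predict.da_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  scores <- vapply(1:2, function(k) {
    S <- object$covs[[k]]
    ch <- chol(S)
    dev <- sweep(newdata, 2, object$mu[[k]])
    z <- backsolve(ch, t(dev), transpose = TRUE)
    maha <- colSums(z^2)
    -0.5 * maha - sum(log(diag(ch))) + log(object$prior[k])
  }, numeric(nrow(newdata)))
  scores <- matrix(scores, nrow = nrow(newdata))
  object$classes[max.col(scores, ties.method = "first")]
}

#' Cross-validated discriminant classification
#'
#' @param x samples x variables matrix.
#' @param y labels.
#' @param kind `"linear"` or `"quadratic"`.
#' @param folds fold ids ([make_folds()]); default leave-one-out.
#' @param positive positive-class label for [evaluate()].
#' @return list: `result` ([eval_result()]), `predictions`.
#' @export
da_classify <- function(x, y, kind = c("linear", "quadratic"),
                        folds = NULL, positive = NULL) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  y <- as.character(y)
  if (is.null(folds)) folds <- make_folds(y, "loocv")
  if (is.null(positive)) positive <- sort(unique(y))[2]
  pred <- character(length(y))
  for (f in unique(folds)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2L)
      stop("a training fold lost one class; use stratified folds")
    fit <- da_fit(x[tr, , drop = FALSE], y[tr], kind)
    pred[!tr] <- predict(fit, x[!tr, , drop = FALSE])
  }
  list(result = evaluate(pred, y, positive), predictions = pred)
}

#' Principal component projection
#'
#' Centred (optionally standardized) PCA; components are ordered by
#' decreasing explained variance.
#'
#' @param x samples x variables matrix.
#' @param n_components components to return; must not exceed the rank.
#' @param scale. standardize variables first.
#' @return list: `scores` (n x n_components), `explained` (variance shares),
#'   `rotation`, `center`, `scale`.
#' @export
pca_project <- function(x, n_components = 2L, scale. = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 samples")
  if (scale.) {
    sds <- apply(x, 2, sd)
    x <- x[, sds > 0, drop = FALSE]
  }
  p <- prcomp(x, center = TRUE, scale. = scale.)
  rank <- sum(p$sdev > max(p$sdev) * 1e-8)
  if (n_components > rank)
    stop_field("n_components", sprintf("exceeds data rank %d", rank))
  list(scores = p$x[, seq_len(n_components), drop = FALSE],
       explained = p$sdev^2 / sum(p$sdev^2),
       rotation = p$rotation[, seq_len(n_components), drop = FALSE],
       center = p$center, scale = if (scale.) p$scale else NULL)
}
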