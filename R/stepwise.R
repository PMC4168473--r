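# Forward stepwise discriminant analysis with Wilks' lambda partial-F
# entry/removal, the SPSS-style procedure used in chemometrics.

wilks_lambda <- function(x, y) {
  # x: n x p matrix (p >= 1); two groups
  n <- nrow(x)
  tot <- sweep(x, 2, colMeans(x))
  Tm <- crossprod(tot)
  W <- matrix(0, ncol(x), ncol(x))
  for (g in unique(y)) {
    xg <- x[y == g, , drop = FALSE]
    W <- W + crossprod(sweep(xg, 2, colMeans(xg)))
  }
  dT <- det(Tm)
  if (!is.finite(dT) || dT <= 0) return(NA_real_)
  det(W) / dT
}

#' Stepwise discriminant analysis
#'
#' Forward entry with backward removal driven by the Wilks' lambda partial-F
#' statistic: at each step the candidate with the largest entry F joins if
#' it exceeds the `entry_alpha` critical value, then included variables
#' whose removal F falls below the `removal_alpha` critical value leave.
#' The final model is a cross-validated LDA on the selected set.
#'
#' @param features feature table (data.frame with `subject_id`, `group`) or
#'   a plain samples x variables matrix.
#' @param y labels (taken from `features$group` when absent).
#' @param entry_alpha,removal_alpha significance levels for entry/removal
#'   (defaults 0.05 / 0.10).
#' @param folds CV folds for the final LDA (default leave-one-out).
#' @param positive positive-class label.
#' @param max_steps safety cap on entered variables.
#' @param standardize z-score features first (default TRUE).
#' @return list: `selected` (ordered names), `result` ([eval_result()]),
#'   `predictions`, `history` (data.frame of steps).
#' @export
stepwise_da <- function(features, y = NULL, entry_alpha = 0.05,
                        removal_alpha = 0.10, folds = NULL, positive = NULL,
                        max_steps = 20L, standardize = TRUE, cv = TRUE) {
  fm <- as_feature_matrix(features, y)
  x <- fm$x; y <- fm$y
  if (standardize) x <- zscore(x)
  n <- nrow(x); g <- 2L
  cand <- colnames(x)
  sel <- character(0)
  hist <- list()
  lam_cur <- 1
  # For two groups, Wilks' lambda of a variable set equals RSS/TSS of the
  # regression of the group indicator on those variables, and the partial F
  # of entry equals the regression partial F (verified in the test suite
  # against the determinant form). Candidates are therefore scanned via
  # incremental Gram-Schmidt residualization: O(n * F) per step.
  yi <- as.numeric(y == sort(unique(y))[2])
  yr <- yi - mean(yi)
  tss <- sum(yr^2)
  xr <- sweep(x, 2, colMeans(x))          # residualized candidates
  xnorm0 <- colSums(xr^2)
  active <- rep(TRUE, length(cand))
  names(active) <- cand
  repeat {
    p <- length(sel)
    # stop when out of error degrees of freedom for the partial F
    if (!any(active) || p >= max_steps || n - g - p < 2L) break
    x2 <- colSums(xr[, active, drop = FALSE]^2)
    ok <- x2 > 1e-10 * pmax(xnorm0[active], 1e-300)   # collinearity guard
    xy <- colSums(xr[, active, drop = FALSE] * yr)
    r2 <- ifelse(ok, xy^2 / (x2 * sum(yr^2)), 0)
    r2 <- pmin(r2, 1 - 1e-12)
    Fent <- (n - g - p) / (g - 1) * r2 / (1 - r2)
    best <- which.max(Fent)
    Fcrit <- qf(1 - entry_alpha, g - 1, n - g - p)
    if (!length(best) || !is.finite(Fent[best]) || Fent[best] < Fcrit) break
    v <- names(Fent)[best]
    lam_cur <- lam_cur * (1 - r2[best])
    sel <- c(sel, v)
    active[v] <- FALSE
    q <- xr[, v] / sqrt(sum(xr[, v]^2))
    yr <- yr - q * sum(q * yr)
    xr[, active] <- xr[, active, drop = FALSE] -
      q %*% crossprod(q, xr[, active, drop = FALSE])
    hist[[length(hist) + 1L]] <- data.frame(
      step = length(hist) + 1L, action = "enter", variable = v,
      F_value = unname(Fent[best]), wilks = lam_cur)
    # removal pass (small model: determinant form is cheap here)
    repeat {
      p <- length(sel)
      if (p < 2L) break
      lam_drop <- vapply(sel, function(v) {
        wilks_lambda(x[, setdiff(sel, v), drop = FALSE], y)
      }, numeric(1))
      Frem <- (n - g - p + 1) / (g - 1) * (lam_drop / lam_cur - 1)
      worst <- which.min(Frem)
      Fcrit_r <- qf(1 - removal_alpha, g - 1, n - g - p + 1)
      if (Frem[worst] >= Fcrit_r) break
      hist[[length(hist) + 1L]] <- data.frame(
        step = length(hist) + 1L, action = "remove",
        variable = sel[worst], F_value = unname(Frem[worst]),
        wilks = lam_drop[worst])
      lam_cur <- lam_drop[worst]
      sel <- setdiff(sel, sel[worst])
      # re-residualize remaining candidates against the reduced model
      Zs <- qr.Q(qr(cbind(1, x[, sel, drop = FALSE])))
      yr <- drop(yi - Zs %*% crossprod(Zs, yi))
      xr <- x - Zs %*% crossprod(Zs, x)
    }
  }
  if (is.null(positive)) positive <- sort(unique(y))[2]
  hist_df <- if (length(hist)) do.call(rbind, hist) else data.frame()
  if (!length(sel)) {
    warning("no feature met the entry criterion; chance-level result")
    if (!cv) return(list(selected = character(0), result = NULL,
                         predictions = NULL, history = hist_df))
    if (is.null(folds)) folds <- make_folds(y, "loocv")
    pred <- majority_predict(y, folds)
    return(list(selected = character(0),
                result = evaluate(pred, y, positive),
                predictions = pred,
                history = hist_df))
  }
  if (!cv) return(list(selected = sel, result = NULL, predictions = NULL,
                       history = hist_df))
  fit <- da_classify(x[, sel, drop = FALSE], y, "linear", folds, positive)
  list(selected = sel, result = fit$result, predictions = fit$predictions,
       history = hist_df)
}

# prior-based fallback predictions per fold; ties -> first sorted class
majority_predict <- function(y, folds) {
  pred <- character(length(y))
  classes <- sort(unique(y))
  for (f in unique(folds)) {
    tr <- folds != f
    cnt <- vapply(classes, function(g) sum(y[tr] == g), numeric(1))
    pred[!tr] <- classes[which.max(cnt)]
  }
  pred
}

as_feature_matrix <- function(features, y = NULL) {
  if (is.data.frame(features) && all(c("subject_id", "group") %in%
                                     names(features))) {
    if (is.null(y)) y <- as.character(features$group)
    x <- as.matrix(features[, setdiff(names(features),
                                      c("subject_id", "group")),
                            drop = FALSE])
    rownames(x) <- features$subject_id
  } else {
    x <- as.matrix(features)
    if (is.null(y)) stop("labels `y` required for a plain matrix")
    y <- as.character(y)
  }
  if (nrow(x) != length(y)) stop("labels do not match rows")
  list(x = x, y = y)
}

zscore <- function(x) {
  mu <- colMeans(x)
  sds <- apply(x, 2, sd)
  sds[sds == 0] <- 1
  scale(x, center = mu, scale = sds)
}
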