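test_that("metric identities hold for random confusion matrices", {
  set.seed(11)
  for (i in 1:50) {
    cnt <- rmultinom(1, size = sample(10:200, 1), prob = runif(4))
    er <- eval_result(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(er$sensitivity, cnt[1] / (cnt[1] + cnt[4]))
    expect_equal(er$specificity, cnt[2] / (cnt[2] + cnt[3]))
    expect_equal(er$accuracy, (cnt[1] + cnt[2]) / sum(cnt))
  }
})

test_that("evaluate handles degenerate and erroneous inputs", {
  truth <- rep(c("B", "A"), each = 4)
  allB <- rep("B", 8)
  er <- evaluate(allB, truth, positive = "B")
  expect_equal(er$sensitivity, 1)
  expect_equal(er$specificity, 0)
  expect_error(evaluate(allB[1:5], truth, "B"), "length")
  expect_error(evaluate(rep("C", 8), truth, "B"), "unseen")
  expect_error(evaluate(allB, truth, "Z"), "absent")
})

test_that("stratified folds balance classes; loocv is one per sample", {
  y <- rep(c("A", "B"), each = 20)
  expect_identical(make_folds(y, "loocv"), 1:40)
  f <- make_folds(y, "stratified", k = 5, seed = 2)
  for (k in 1:5) expect_identical(sum(y[f == k] == "A"), 4L)
  expect_identical(make_folds(y, "stratified", k = 5, seed = 2), f)
  expect_error(make_folds(y, "stratified", k = 50), "k")
})

test_that("pca_project: collinear data, duplicated columns, rank errors", {
  set.seed(12)
  t_ <- rnorm(30)
  line3d <- cbind(t_, 2 * t_, -t_)                 # data on a line
  p <- pca_project(line3d, 1)
  expect_equal(p$explained[1], 1, tolerance = 1e-10)
  expect_error(pca_project(line3d, 3), "rank")

  x <- matrix(rnorm(60), 30)
  dup <- cbind(a = x[, 1], b = x[, 2], a2 = x[, 1])
  p2 <- pca_project(dup, 2)
  expect_equal(abs(p2$rotation["a", ]), abs(p2$rotation["a2", ]),
               tolerance = 1e-10)
})

test_that("discriminant analysis separates well-separated clouds", {
  g <- gauss_features(n_per_group = 15, delta = 8, seed = 21)
  for (kind in c("linear", "quadratic")) {
    res <- da_classify(g$x, g$y, kind)
    expect_equal(res$result$accuracy, 1.0)
  }
})

test_that("LDA/QDA agree with the MASS reference implementation", {
  g <- gauss_features(n_per_group = 15, delta = 2, seed = 22)
  fit <- da_fit(g$x, g$y, "linear")
  ref <- MASS::lda(g$x, grouping = g$y)
  expect_identical(predict(fit, g$x),
                   as.character(predict(ref, g$x)$class))
  fitq <- da_fit(g$x, g$y, "quadratic")
  refq <- MASS::qda(g$x, grouping = g$y)
  expect_identical(predict(fitq, g$x),
                   as.character(predict(refq, g$x)$class))
})

test_that("singular covariance falls back to logged shrinkage", {
  g <- gauss_features(n_per_group = 10, n_noise = 2, seed = 23)
  x <- cbind(g$x, dup = g$x[, 1])                 # exact collinearity
  expect_message(fit <- da_fit(x, g$y, "linear"), "shrinkage")
  expect_length(predict(fit, x), 20L)
})

test_that("LDA and QDA decisions agree under equal covariances at large n", {
  set.seed(24)
  n <- 500
  x <- rbind(matrix(rnorm(2 * n), n), sweep(matrix(rnorm(2 * n), n), 2,
                                            c(-1.5, 1), `+`))
  y <- rep(c("A", "B"), each = n)
  pl <- predict(da_fit(x, y, "linear"), x)
  pq <- predict(da_fit(x, y, "quadratic"), x)
  expect_gt(mean(pl == pq), 0.98)
})

test_that("DA accuracy on permuted labels stays at chance", {
  set.seed(25)
  x <- matrix(rnorm(40 * 5), 40)
  y0 <- rep(c("A", "B"), each = 20)
  correct <- 0; total <- 0
  for (i in 1:100) {
    y <- sample(y0)
    folds <- make_folds(y, "stratified", k = 5, seed = i)
    res <- da_classify(x, y, "linear", folds)
    correct <- correct + res$result$tp + res$result$tn
    total <- total + 40
  }
  p_hat <- correct / total
  expect_lt(abs(p_hat - 0.5), 1.96 * sqrt(0.25 / total))
})

test_that("stepwise entry statistics match the determinant-form oracle", {
  g <- gauss_features(n_per_group = 12, n_noise = 4, delta = 1.5, seed = 31)
  x <- scale(g$x)
  sw <- stepwise_da(x, g$y, entry_alpha = 0.99, removal_alpha = 0.995,
                    standardize = FALSE, cv = FALSE)
  ent <- sw$history[sw$history$action == "enter", ]
  n <- nrow(x)
  for (r in seq_len(min(3, nrow(ent)))) {
    S <- ent$variable[seq_len(r)]
    lam_prev <- if (r == 1) 1 else wilks_det(x[, S[-r], drop = FALSE], g$y)
    lam <- wilks_det(x[, S, drop = FALSE], g$y)
    Fo <- (n - 2 - (r - 1)) * (lam_prev / lam - 1)
    expect_equal(ent$F_value[r], Fo, tolerance = 1e-8)
    expect_equal(ent$wilks[r], lam, tolerance = 1e-8)
  }
})

test_that("stepwise finds the informative feature first (MC over 200 seeds)", {
  hits <- 0L
  for (s in 1:200) {
    g <- gauss_features(n_per_group = 20, n_noise = 20, delta = 3, seed = s)
    sw <- stepwise_da(g$x, g$y, cv = FALSE)
    hits <- hits + (length(sw$selected) > 0 && sw$selected[1] == "inf")
  }
  expect_gte(hits / 200, 0.95)
})

test_that("stepwise handles identical features and empty selections", {
  set.seed(33)
  v <- c(rnorm(10), rnorm(10, 4))
  x <- cbind(a = v, b = v, c = v)
  y <- rep(c("A", "B"), each = 10)
  sw <- stepwise_da(x, y, cv = FALSE)
  expect_length(sw$selected, 1L)

  noise <- matrix(rnorm(40), 20, dimnames = list(NULL, paste0("n", 1:2)))
  expect_warning(
    sw0 <- stepwise_da(noise, y, entry_alpha = 1e-12,
                       folds = make_folds(y, "stratified", k = 5, seed = 1)),
    "entry criterion")
  expect_length(sw0$selected, 0L)
  expect_equal(sw0$result$accuracy, 0.5)
})

test_that("svm separates margin data and detects overfit via CV", {
  g <- gauss_features(n_per_group = 10, n_noise = 1, delta = 10, seed = 41)
  gs <- svm_grid_search(g$x, g$y)
  expect_equal(gs$cv_accuracy, 1.0)

  # pure noise + tiny sigma: resubstitution is perfect, CV near chance
  set.seed(42)
  xn <- matrix(rnorm(30 * 2), 30, dimnames = list(NULL, c("u", "v")))
  yn <- rep(c("A", "B"), each = 15)
  enc <- ifelse(yn == "B", 1L, -1L)
  D <- as.matrix(dist(xn))^2
  resub <- enoser:::.cpp_svm_train_predict(D, enc, 100, 0.05, D)
  expect_equal(mean(resub == enc), 1.0)
  cv <- svm_classify(xn, yn, C = 100, sigma = 0.05)
  expect_lt(cv$result$accuracy, 0.75)
})

test_that("grid-search ties break to smaller C then smaller sigma", {
  g <- gauss_features(n_per_group = 8, n_noise = 1, delta = 10, seed = 43)
  gs <- svm_grid_search(g$x, g$y, C_grid = c(10, 1, 100),
                        sigma_grid = c(5, 1))
  # many grid points reach accuracy 1; the reported one is the smallest
  best <- gs$grid[gs$grid$accuracy == max(gs$grid$accuracy), ]
  expect_equal(gs$C, min(best$C))
  expect_equal(gs$sigma, min(best$sigma[best$C == gs$C]))
  expect_error(svm_grid_search(g$x, g$y, C_grid = numeric(0)), "C_grid")
  expect_error(svm_grid_search(g$x, g$y, sigma_grid = -1), "sigma_grid")
})

test_that("greedy selection: trace bookkeeping, ties, reproducibility", {
  g <- gauss_features(n_per_group = 10, n_noise = 3, delta = 3, seed = 44)
  tr <- greedy_svm_selection(g$x, g$y, C = 10, sigma = 2, max_indices = 10)
  expect_identical(nrow(tr), min(10L, ncol(g$x)))   # trace length rule
  expect_identical(anyDuplicated(tr$index_name), 0L)
  expect_identical(attr(tr, "C"), 10)

  tr2 <- greedy_svm_selection(g$x, g$y, C = 10, sigma = 2, max_indices = 10)
  expect_identical(as.data.frame(tr), as.data.frame(tr2))  # deterministic

  # duplicated informative column: lexicographically first name wins
  xdup <- cbind(zz_first = g$x[, "inf"], g$x)
  colnames(xdup)[colnames(xdup) == "inf"] <- "aa_dup"
  tr3 <- greedy_svm_selection(xdup, g$y, C = 10, sigma = 2, max_indices = 2)
  expect_identical(tr3$index_name[1], "aa_dup")
})
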