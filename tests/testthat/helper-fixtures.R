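# Shared fixtures, built in code at test time.

# small cohort for pipeline plumbing tests
small_spec <- function(seed = 42L, ...) {
  cohort_spec(n_per_group = 4L, n_sweeps = 3L, seed = seed, ...)
}

small_curves <- function(seed = 42L, ...) {
  representative_curves(generate_cohort(small_spec(seed, ...)))
}

# deterministic smooth test curve on the default grid
bump_curve <- function(grid = default_grid(), centre = 260, width = 30,
                       amp = 1, offset = 0.2) {
  offset + amp * exp(-(grid - centre)^2 / (2 * width^2))
}

# two-class Gaussian feature matrix: first column informative
gauss_features <- function(n_per_group = 20, n_noise = 5, delta = 3,
                           seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_group
    x <- cbind(inf = c(rnorm(n_per_group, 0), rnorm(n_per_group, delta)),
               matrix(rnorm(n * n_noise), n,
                      dimnames = list(NULL,
                                      paste0("noise", seq_len(n_noise)))))
    list(x = x, y = rep(c("A", "B"), each = n_per_group))
  })
}

# determinant-form Wilks lambda: the independent oracle for the stepwise
# scan (which uses the regression equivalence)
wilks_det <- function(x, y) {
  x <- as.matrix(x)
  tot <- sweep(x, 2, colMeans(x))
  Tm <- crossprod(tot)
  W <- matrix(0, ncol(x), ncol(x))
  for (g in unique(y)) {
    xg <- x[y == g, , drop = FALSE]
    W <- W + crossprod(sweep(xg, 2, colMeans(xg)))
  }
  det(W) / det(Tm)
}
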