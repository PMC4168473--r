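test_that("linear interpolation: midpoint, identity, error bound", {
  expect_equal(interpolate_sweep(c(200, 210), c(1, 3), 205), 2.0)

  grid <- seq(200, 210, by = 1)
  v <- rnorm(length(grid))
  expect_identical(interpolate_sweep(grid, v, grid), v)

  # quadratic oracle: linear interpolation of f(t)=t^2 sampled at spacing dt
  # has max error dt^2/8 * max|f''| = dt^2/4; assert the stated 2x bound
  dt <- 2
  samp_t <- seq(0, 20, by = dt)
  dense <- seq(0, 20, by = 0.05)
  est <- interpolate_sweep(samp_t, samp_t^2, dense)
  err <- max(abs(est - dense^2))
  expect_lte(err, dt^2 / 4 * 2)
  expect_gt(err, 0)
})

test_that("interpolation refuses extrapolation, naming the endpoint", {
  expect_error(interpolate_sweep(c(200, 210), c(1, 2), c(195, 205)), "195")
  expect_error(interpolate_sweep(c(200, 210), c(1, 2), c(205, 215)), "215")
  expect_error(interpolate_sweep(c(210, 200), c(1, 2), 205),
               "strictly increasing")
  expect_error(interpolate_sweep(200, 1, 200), "at least 2")
})

test_that("averaging: mean of one, constants, permutation invariance", {
  v <- rnorm(10)
  expect_identical(average_sweeps(list(v))$values, v)
  expect_identical(average_sweeps(list(v))$n_sweeps_averaged, 1L)

  two <- average_sweeps(list(rep(1, 5), rep(3, 5)))
  expect_equal(two$values, rep(2, 5))

  sw <- lapply(1:6, function(i) rnorm(8))
  expect_equal(average_sweeps(sw)$values,
               average_sweeps(rev(sw))$values)
  expect_error(average_sweeps(list()), "no sweeps")
})

test_that("averaging 10 noisy sweeps shrinks noise like 1/sqrt(10)", {
  # Monte-Carlo oracle over 500 replicates
  set.seed(101)
  grid <- default_grid()
  truth <- bump_curve(grid)
  s <- 0.05
  resid <- replicate(500, {
    sweeps <- lapply(1:10, function(i) truth + rnorm(length(grid), 0, s))
    average_sweeps(sweeps)$values - truth
  })
  expect_equal(sd(resid), s / sqrt(10), tolerance = 0.05)
})

test_that("interpolate-then-average equals average-then-interpolate", {
  # exact commutation for linear operations on a shared raw raster
  raw_t <- sort(c(195, 355, runif(40, 196, 354)))
  grid <- default_grid()
  sweeps <- lapply(1:4, function(i) rnorm(length(raw_t)))
  via_interp <- average_sweeps(lapply(sweeps, function(v)
    interpolate_sweep(raw_t, v, grid)))$values
  via_avg <- interpolate_sweep(raw_t, colMeans(do.call(rbind, sweeps)), grid)
  expect_equal(via_interp, via_avg, tolerance = 1e-12)
})

test_that("representative_curves averages per subject and layer on the grid", {
  sw <- generate_cohort(small_spec())
  cur <- representative_curves(sw)
  grid <- default_grid()
  expect_identical(sort(unique(cur$temperature_c)), grid)
  one <- cur[cur$subject_id == "S001" & cur$layer == 1L, ]
  expect_identical(nrow(one), length(grid))
  expect_identical(unique(one$n_sweeps_averaged), 3L)
  # direct recomputation for that subject/layer
  raw <- sw[sw$subject_id == "S001" & sw$layer == 1L, ]
  vals <- lapply(split(raw, raw$sweep), function(d)
    interpolate_sweep(d$temperature_c, d$conductance, grid))
  expect_equal(one$conductance[order(one$temperature_c)],
               average_sweeps(vals)$values, tolerance = 1e-12)
  # sweep-subset hook
  cur2 <- representative_curves(sw, use_sweeps = 2:3)
  expect_identical(unique(cur2$n_sweeps_averaged), 2L)
})

test_that("curves survive a CSV round-trip", {
  cur <- small_curves()
  path <- withr::local_tempfile(fileext = ".csv")
  write_curves(cur, path)
  back <- read_curves(path)
  expect_identical(back$conductance, cur$conductance)
})
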