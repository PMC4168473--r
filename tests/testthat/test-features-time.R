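grid160 <- default_grid()  # 195..355, 161 points

test_that("total area: rectangle, triangle, Gaussian vs closed form", {
  expect_equal(total_area(grid160, rep(2, 161)), 320)
  expect_equal(total_area(grid160, seq(0, 1, length.out = 161)), 80)
  # Gaussian bump against the erf integral
  mu <- 260; s <- 20
  v <- exp(-(grid160 - mu)^2 / (2 * s^2))
  exact <- s * sqrt(2 * pi) * (pnorm(355, mu, s) - pnorm(195, mu, s))
  expect_equal(total_area(grid160, v), exact, tolerance = 1e-3)
})

test_that("subarea counts and uniformity on the 160 degC span", {
  v <- rep(3, 161)
  s10 <- subareas(grid160, v, 10)
  s40 <- subareas(grid160, v, 40)
  expect_length(s10, 16L)
  expect_length(s40, 4L)
  expect_equal(unname(s10), rep(total_area(grid160, v) / 16, 16))
  expect_error(subareas(grid160, v, 170), "wider")
  expect_error(subareas(grid160, v, 7), "divide")
})

test_that("subareas are additive to 1e-9 relative", {
  set.seed(5)
  for (i in 1:5) {
    v <- bump_curve(grid160, centre = runif(1, 220, 330),
                    width = runif(1, 15, 50)) + rnorm(161, 0, 0.05)
    s10 <- subareas(grid160, v, 10)
    s40 <- subareas(grid160, v, 40)
    tot <- total_area(grid160, v)
    expect_equal(sum(s10), tot, tolerance = 1e-9)
    for (k in 1:4)
      expect_equal(s40[[k]], sum(s10[(4 * k - 3):(4 * k)]),
                   tolerance = 1e-9)
  }
})

test_that("steepest slope: affine curve and first-window tie rule", {
  m <- 0.25
  v <- m * (grid160 - 195) + 1
  for (p in c(3L, 5L)) {
    sl <- steepest_slope(grid160, v, p)
    expect_equal(unname(sl["max_slope"]), m, tolerance = 1e-12)
    expect_equal(unname(sl["tmax"]), 195 + (p - 1) / 2)  # first window centre
  }
  expect_error(steepest_slope(grid160[1:2], c(1, 2), 3L), "shorter")
})

test_that("steepest slope matches an exhaustive least-squares scan", {
  set.seed(8)
  v <- c(rep(0, 80), rep(1, 81)) + rnorm(161, 0, 0.01)  # step curve
  for (p in c(3L, 5L)) {
    slopes <- sapply(seq_len(161 - p + 1), function(i) {
      w <- i:(i + p - 1)
      unname(coef(lm(v[w] ~ grid160[w]))[2])
    })
    best <- which.max(slopes)
    sl <- steepest_slope(grid160, v, p)
    expect_equal(unname(sl["max_slope"]), slopes[best], tolerance = 1e-9)
    expect_equal(unname(sl["tmax"]), grid160[best] + (p - 1) / 2)
    # the maximizing window straddles the step at index 81
    expect_true(best <= 81 && best + p - 1 >= 81)
  }
})

test_that("slope keeps its sign on downward-trending curves", {
  v <- seq(10, 0, length.out = 161)
  sl <- steepest_slope(grid160, v, 3L)
  expect_lte(unname(sl["max_slope"]), 0)
})

test_that("scale and temperature-shift equivariance", {
  set.seed(9)
  v <- bump_curve(grid160) + rnorm(161, 0, 0.02)
  c0 <- 3.7
  expect_equal(total_area(grid160, c0 * v), c0 * total_area(grid160, v))
  expect_equal(subareas(grid160, c0 * v, 10), c0 * subareas(grid160, v, 10))
  sl <- steepest_slope(grid160, v, 5L)
  sls <- steepest_slope(grid160, c0 * v, 5L)
  expect_equal(unname(sls["max_slope"]), c0 * unname(sl["max_slope"]))
  expect_equal(unname(sls["tmax"]), unname(sl["tmax"]))
  # shifting the grid shifts tmax, leaves areas
  shifted <- grid160 + 50
  expect_equal(total_area(shifted, v), total_area(grid160, v))
  expect_equal(unname(steepest_slope(shifted, v, 5L)["tmax"]),
               unname(sl["tmax"]) + 50)
})

test_that("time_features yields 75 well-named indices per the grammar", {
  tf <- time_features(small_curves())
  idx <- setdiff(names(tf), c("subject_id", "group"))
  expect_length(idx, 75L)
  expect_true(all(c("AS1", "A10S2_10", "A40S3_4", "Max_slope_3_S1",
                    "Tmax_slope_5_S3") %in% idx))
  expect_identical(anyDuplicated(idx), 0L)
  expect_false(anyNA(tf[idx]))
  # feature table round-trip
  path <- withr::local_tempfile(fileext = ".csv")
  write_features(tf, path)
  expect_equal(read_features(path), tf, tolerance = 1e-15)
})
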