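test_that("default-design cohort has the study's dimensions", {
  sw <- generate_cohort(cohort_spec(seed = 3L))
  expect_length(unique(sw$subject_id), 40L)
  key <- unique(as.data.frame(sw)[c("subject_id", "layer", "sweep")])
  expect_identical(nrow(key), 1200L)             # 40 x 10 x 3
  expect_identical(sort(unique(sw$group)), c("A", "B"))
  expect_identical(range(sw$sweep), c(1L, 10L))
  expect_identical(sort(unique(sw$layer)), 1:3)
  expect_true(min(sw$temperature_c) >= 195 && max(sw$temperature_c) <= 355)
})

test_that("generation is deterministic in the seed and varies across seeds", {
  a <- generate_cohort(small_spec(seed = 7L))
  b <- generate_cohort(small_spec(seed = 7L))
  c <- generate_cohort(small_spec(seed = 8L))
  expect_identical(a$conductance, b$conductance)
  expect_identical(a$temperature_c, b$temperature_c)
  expect_false(identical(a$conductance, c$conductance))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(generate_cohort(small_spec())); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("invalid specs fail naming the violated field", {
  expect_error(cohort_spec(n_per_group = 1), "n_per_group")
  expect_error(cohort_spec(temp_end_c = 100), "temp_end_c")
  expect_error(cohort_spec(temp_step_c = 0), "temp_step_c")
  expect_error(cohort_spec(effect_window = c(150, 170)), "effect_window")
  expect_error(cohort_spec(effect_window = c(-5, 10)), "effect_window")
  expect_error(cohort_spec(effect_layer = 9), "effect_layer")
  expect_error(cohort_spec(sweep_noise_sd = -1), "sweep_noise_sd")
})

test_that("group effect is localized to the configured window and layer", {
  # >= 200 subjects so the regional mean difference is well resolved
  spec <- cohort_spec(n_per_group = 100L, n_sweeps = 2L,
                      effect_layer = 2L, effect_window = c(90, 100),
                      effect_size = 3, seed = 13L)
  cur <- representative_curves(generate_cohort(spec))
  shift <- spec$effect_size * spec$subject_sd
  rel <- cur$temperature_c - spec$temp_start_c
  # linear interpolation of the step edge smears the boundary by up to one
  # raw raster step (~2 degC + jitter); keep a 3 degC margin on both sides
  inside <- cur$layer == 2L & rel >= 93 & rel < 97
  outside <- !(cur$layer == 2L & rel >= 87 & rel < 103)
  # grid points within a subject share the subject random effect, so the
  # sampling unit for the SE is the per-subject regional mean
  for (region in list(inside, outside)) {
    sub_mean <- tapply(cur$conductance[region],
                       cur$subject_id[region], mean)
    grp <- subject_labels(cur)
    grp <- grp$group[match(names(sub_mean), grp$subject_id)]
    a <- sub_mean[grp == "A"]; b <- sub_mean[grp == "B"]
    d <- mean(b) - mean(a)
    se <- sqrt(var(a) / length(a) + var(b) / length(b))
    target <- if (identical(region, inside)) shift else 0
    expect_lt(abs(d - target), 3 * se + 1e-12)
  }
})

test_that("sweeps survive a CSV round-trip at full precision", {
  sw <- generate_cohort(small_spec())
  path <- withr::local_tempfile(fileext = ".csv")
  write_sweeps(sw, path)
  back <- read_sweeps(path)
  expect_identical(back$conductance, sw$conductance)
  expect_identical(back$temperature_c, sw$temperature_c)
  expect_identical(back$subject_id, sw$subject_id)
})

test_that("resistance convention stores the reciprocal signal", {
  g <- generate_cohort(small_spec(signal = "conductance"))
  r <- generate_cohort(small_spec(signal = "resistance"))
  expect_equal(r$conductance, 1 / g$conductance, tolerance = 1e-12)
})
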