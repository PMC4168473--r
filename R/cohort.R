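#' Specify a synthetic eNose cohort
#'
#' Describes a two-group study in which every subject is measured repeatedly
#' with a multi-layer metal-oxide sensor whose heater sweeps a temperature
#' range. Defaults mirror the emulated study design: 2 x 20 subjects, 10
#' sweeps per subject, 3 sensor layers, heater span 195-355 degC. Group "B"
#' curves carry an additive shift of `effect_size * subject_sd` conductance
#' units inside `effect_window` (half-open, in relative degrees, i.e. degC
#' above `temp_start_c`) on `effect_layer` only.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param n_sweeps repeated sweeps per subject.
#' @param layers number of sensor layers.
#' @param temp_start_c,temp_end_c,temp_step_c heater span and the step of the
#'   equidistant analysis grid, degC.
#' @param effect_layer layer carrying the group difference.
#' @param effect_window numeric length-2, half-open window `[lo, hi)` in
#'   relative degC within which group B is shifted.
#' @param effect_size standardized mean shift (in units of `subject_sd`).
#' @param subject_sd SD of the per-subject random effect on baseline bump
#'   amplitudes, conductance a.u.
#' @param sweep_noise_sd SD of additive per-sample sweep noise, a.u.
#' @param signal `"conductance"` (default) or `"resistance"`; the latter
#'   stores the reciprocal signal, a convention flag for instruments that log
#'   resistance.
#' @param seed integer seed; fixed seed gives bit-identical cohorts.
#' @return object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_per_group = 20L, n_sweeps = 10L, layers = 3L,
                        temp_start_c = 195, temp_end_c = 355, temp_step_c = 1,
                        effect_layer = 2L, effect_window = c(90, 100),
                        effect_size = 3, subject_sd = 0.1,
                        sweep_noise_sd = 0.05,
                        signal = c("conductance", "resistance"),
                        seed = 1L) {
  signal <- match.arg(signal)
  spec <- list(
    n_per_group = as.integer(n_per_group), n_sweeps = as.integer(n_sweeps),
    layers = as.integer(layers), temp_start_c = temp_start_c,
    temp_end_c = temp_end_c, temp_step_c = temp_step_c,
    effect_layer = as.integer(effect_layer),
    effect_window = as.numeric(effect_window), effect_size = effect_size,
    subject_sd = subject_sd, sweep_noise_sd = sweep_noise_sd,
    signal = signal, seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (spec$n_per_group < 2L)
    stop_field("n_per_group", "must be >= 2 so both classes are represented")
  if (spec$n_sweeps < 1L) stop_field("n_sweeps", "must be >= 1")
  if (spec$layers < 1L) stop_field("layers", "must be >= 1")
  if (!(spec$temp_end_c > spec$temp_start_c))
    stop_field("temp_end_c", "must exceed temp_start_c")
  if (!(spec$temp_step_c > 0)) stop_field("temp_step_c", "must be > 0")
  span <- spec$temp_end_c - spec$temp_start_c
  w <- spec$effect_window
  if (length(w) != 2L || w[2] <= w[1])
    stop_field("effect_window", "must be (lo, hi) with hi > lo")
  if (w[1] < 0 || w[2] > span)
    stop_field("effect_window", sprintf(
      "must lie within [0, %g) relative degC", span))
  if (spec$effect_layer < 1L || spec$effect_layer > spec$layers)
    stop_field("effect_layer", "must index an existing layer")
  if (spec$subject_sd < 0) stop_field("subject_sd", "must be >= 0")
  if (spec$sweep_noise_sd < 0) stop_field("sweep_noise_sd", "must be >= 0")
  invisible(spec)
}

# Baseline bump parameters per layer (absolute degC). Amplitudes in a.u.;
# layers recycle if more than 3 are requested. Chosen to match the plotted
# morphology of broadband SnO2 layers: smooth, 1-2 humps over the span.
layer_baselines <- function() {
  list(
    list(amp = c(1.0, 0.6), mu = c(240, 310), sd = c(30, 25), offset = 0.20),
    list(amp = 1.2,         mu = 260,         sd = 35,        offset = 0.25),
    list(amp = c(0.8, 0.9), mu = c(225, 300), sd = c(25, 30), offset = 0.15)
  )
}

baseline_curve <- function(temp, layer, amp_offsets = 0) {
  b <- layer_baselines()[[(layer - 1L) %% 3L + 1L]]
  amps <- b$amp + amp_offsets
  v <- rep(b$offset, length(temp))
  for (j in seq_along(amps)) {
    v <- v + amps[j] * exp(-(temp - b$mu[j])^2 / (2 * b$sd[j]^2))
  }
  v
}

#' Generate a synthetic cohort of sensor sweeps
#'
#' Simulates `2 * n_per_group` subjects. Each subject's true curve per layer
#' is a smooth sum of Gaussian bumps whose amplitudes carry a subject-level
#' random effect (`N(0, subject_sd)`); each sweep adds i.i.d. Gaussian sample
#' noise (`N(0, sweep_noise_sd)`). Group B additionally receives a constant
#' conductance shift of `effect_size * subject_sd` inside the configured
#' temperature window on the configured layer. Raw sweeps are sampled on a
#' jittered ~2 degC raster (exact endpoints), so downstream interpolation is
#' exercised on irregular data.
#'
#' @param spec a [cohort_spec()].
#' @return `data.table` with columns `subject_id`, `group` ("A"/"B"),
#'   `sweep`, `layer`, `temperature_c`, `conductance`; one row per sample.
#' @examples
#' sw <- generate_cohort(cohort_spec(n_per_group = 2, n_sweeps = 2))
#' length(unique(sw$subject_id))
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  with_seed(spec$seed, {
    n_sub <- 2L * spec$n_per_group
    ids <- sprintf("S%03d", seq_len(n_sub))
    groups <- rep(c("A", "B"), each = spec$n_per_group)
    shift <- spec$effect_size * spec$subject_sd
    win <- spec$effect_window + spec$temp_start_c  # absolute degC
    base_temps <- seq(spec$temp_start_c, spec$temp_end_c, by = 2)
    n_t <- length(base_temps)
    out <- vector("list", n_sub)
    for (i in seq_len(n_sub)) {
      rows <- vector("list", spec$layers * spec$n_sweeps)
      r <- 0L
      for (l in seq_len(spec$layers)) {
        nb <- length(layer_baselines()[[(l - 1L) %% 3L + 1L]]$amp)
        amp_off <- rnorm(nb, 0, spec$subject_sd)
        for (s in seq_len(spec$n_sweeps)) {
          temps <- base_temps
          if (n_t > 2L) {
            temps[2:(n_t - 1L)] <- temps[2:(n_t - 1L)] +
              runif(n_t - 2L, -0.4, 0.4)
          }
          g <- baseline_curve(temps, l, amp_off)
          if (groups[i] == "B" && l == spec$effect_layer) {
            idx <- temps >= win[1] & temps < win[2]
            g[idx] <- g[idx] + shift
          }
          g <- g + rnorm(n_t, 0, spec$sweep_noise_sd)
          if (spec$signal == "resistance") g <- 1 / g
          r <- r + 1L
          rows[[r]] <- data.table::data.table(
            subject_id = ids[i], group = groups[i], sweep = s, layer = l,
            temperature_c = temps, conductance = g)
        }
      }
      out[[i]] <- data.table::rbindlist(rows)
    }
    sweeps <- data.table::rbindlist(out)
    data.table::setattr(sweeps, "cohort_spec", spec)
    sweeps[]
  })
}

#' Read/write sweeps in the long CSV schema
#'
#' The on-disk schema is one row per sample with header
#' `subject_id, group, sweep, layer, temperature_c, conductance`.
#'
#' @param sweeps long-format sweeps table.
#' @param path CSV file path.
#' @return `write_sweeps()` returns `path` invisibly; `read_sweeps()` the
#'   sweeps `data.table`.
#' @export
write_sweeps <- function(sweeps, path) {
  fwrite_full(sweeps[, c("subject_id", "group", "sweep", "layer",
                         "temperature_c", "conductance")], path)
  invisible(path)
}

#' @rdname write_sweeps
#' @export
read_sweeps <- function(path) {
  need <- c("subject_id", "group", "sweep", "layer",
            "temperature_c", "conductance")
  x <- data.table::fread(path, colClasses = list(
    character = c("subject_id", "group"),
    integer = c("sweep", "layer"),
    numeric = c("temperature_c", "conductance")))
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("sweeps file lacks column(s): ", paste(miss, collapse = ", "))
  x[, need, with = FALSE]
}

#' Group labels of a sweeps or curves table
#'
#' @param x table with `subject_id` and `group` columns.
#' @return data.frame with one row per subject (`subject_id`, `group`),
#'   ordered by subject id.
#' @export
subject_labels <- function(x) {
  u <- unique(data.table::as.data.table(x)[, c("subject_id", "group")])
  u <- u[order(u$subject_id)]
  as.data.frame(u)
}
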