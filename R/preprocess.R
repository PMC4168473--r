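#' Default equidistant temperature grid
#'
#' @param start,end,step grid span and spacing in degC. The default
#'   195-355 degC at 1 degC (161 points) matches the instrument's heater
#'   sweep span.
#' @return numeric vector of temperatures.
#' @export
default_grid <- function(start = 195, end = 355, step = 1) {
  if (!(end > start)) stop_field("end", "must exceed start")
  if (!(step > 0)) stop_field("step", "must be > 0")
  seq(start, end, by = step)
}

#' Linearly interpolate one sweep onto an equidistant grid
#'
#' @param temperature_c,conductance the sweep's samples; temperatures must be
#'   strictly increasing.
#' @param grid target temperatures; must lie within the sampled range (no
#'   extrapolation).
#' @return conductance at each grid point.
#' @export
interpolate_sweep <- function(temperature_c, conductance, grid) {
  if (length(temperature_c) < 2L)
    stop("sweep must have at least 2 samples")
  if (any(diff(temperature_c) <= 0))
    stop("sweep temperatures must be strictly increasing")
  lo <- min(temperature_c); hi <- max(temperature_c)
  if (min(grid) < lo)
    stop(sprintf("grid point %g below sampled range start %g", min(grid), lo))
  if (max(grid) > hi)
    stop(sprintf("grid point %g above sampled range end %g", max(grid), hi))
  approx(temperature_c, conductance, xout = grid, method = "linear",
         ties = "ordered")$y
}

#' Average interpolated sweeps into one representative curve
#'
#' @param sweep_values list (or matrix, sweeps in rows) of conductance
#'   vectors already on a common grid.
#' @return list with `values` (pointwise mean) and `n_sweeps_averaged`.
#' @export
average_sweeps <- function(sweep_values) {
  if (is.list(sweep_values)) {
    if (length(sweep_values) == 0L) stop("no sweeps to average")
    sweep_values <- do.call(rbind, sweep_values)
  }
  if (is.null(dim(sweep_values))) sweep_values <- matrix(sweep_values, nrow = 1L)
  if (nrow(sweep_values) == 0L) stop("no sweeps to average")
  list(values = colMeans(sweep_values), n_sweeps_averaged = nrow(sweep_values))
}

#' Representative curves: interpolate and average every subject x layer
#'
#' Implements the preprocessing stage: each raw sweep is linearly
#' interpolated onto `grid`, then all sweeps of one subject and layer are
#' averaged pointwise.
#'
#' @param sweeps long sweeps table (see [generate_cohort()] /
#'   [read_sweeps()]).
#' @param grid equidistant temperature grid, default [default_grid()].
#' @param use_sweeps optional integer vector restricting which sweep numbers
#'   enter the average (hook for discarding equilibration sweeps; default all).
#' @return long `data.table`: `subject_id`, `group`, `layer`,
#'   `temperature_c`, `conductance`, `n_sweeps_averaged`.
#' @export
representative_curves <- function(sweeps, grid = default_grid(),
                                  use_sweeps = NULL) {
  sweeps <- data.table::as.data.table(sweeps)
  if (!is.null(use_sweeps)) sweeps <- sweeps[sweeps$sweep %in% use_sweeps]
  if (nrow(sweeps) == 0L) stop("no sweeps to average")
  step <- diff(grid)
  if (length(step) && max(abs(step - step[1])) > 1e-9 * abs(step[1]))
    stop_field("grid", "must be equidistant")
  sweep <- layer <- subject_id <- NULL  # data.table NSE
  out <- sweeps[, {
    vals <- lapply(split(seq_len(.N), sweep), function(ii)
      interpolate_sweep(temperature_c[ii], conductance[ii], grid))
    avg <- average_sweeps(vals)
    list(temperature_c = grid, conductance = avg$values,
         n_sweeps_averaged = avg$n_sweeps_averaged)
  }, by = c("subject_id", "group", "layer")]
  data.table::setorderv(out, c("subject_id", "layer", "temperature_c"))
  out[]
}

#' Read/write representative curves CSV
#'
#' Schema: `subject_id, group, layer, temperature_c, conductance`
#' (plus `n_sweeps_averaged` when present).
#'
#' @param curves long curves table.
#' @param path CSV file path.
#' @export
write_curves <- function(curves, path) {
  fwrite_full(curves, path)
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  x <- data.table::fread(path)
  need <- c("subject_id", "group", "layer", "temperature_c", "conductance")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("curves file lacks column(s): ", paste(miss, collapse = ", "))
  x
}

# split long curves into list(subject -> list(layer -> values)) plus grid;
# checks all subjects/layers share the grid
curves_matrixify <- function(curves) {
  curves <- data.table::as.data.table(curves)
  grid <- sort(unique(curves$temperature_c))
  key <- paste(curves$subject_id, curves$layer, sep = "\r")
  n <- length(grid)
  sp <- split(seq_len(nrow(curves)), key)
  bad <- vapply(sp, function(ii) length(ii) != n, logical(1))
  if (any(bad)) stop("curves do not share a common temperature grid")
  labs <- subject_labels(curves)
  layers <- sort(unique(curves$layer))
  val <- function(sid, l) {
    ii <- sp[[paste(sid, l, sep = "\r")]]
    v <- curves$conductance[ii][order(curves$temperature_c[ii])]
    v
  }
  list(grid = grid, labels = labs, layers = layers, value = val)
}
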