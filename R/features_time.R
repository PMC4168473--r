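#' Total area under a representative curve
#'
#' Trapezoidal integral of conductance over the full temperature span; the
#' index `AS{layer}`.
#'
#' @param grid equidistant temperatures, degC.
#' @param values conductance at each grid point.
#' @return scalar area (a.u. x degC).
#' @export
total_area <- function(grid, values) {
  if (length(grid) < 2L) stop("curve needs at least 2 grid points")
  trapz(grid, values)
}

#' Windowed subareas of a curve
#'
#' Trapezoidal integrals over consecutive half-open windows of
#' `window_width` relative degC, k = 1 starting at the low-temperature end —
#' the indices `A{w}S{layer}_{k}`. Adjacent windows share a boundary grid
#' point, so the 10 degC subareas sum exactly to the total area and each
#' 40 degC subarea is the sum of its four 10 degC constituents.
#'
#' @inheritParams total_area
#' @param window_width window size in degC; must divide the span and be a
#'   multiple of the grid step.
#' @return named vector of subareas, names `1..k`.
#' @export
subareas <- function(grid, values, window_width) {
  span <- grid[length(grid)] - grid[1]
  if (window_width > span)
    stop_field("window_width", "wider than the curve span")
  n_win <- span / window_width
  if (abs(n_win - round(n_win)) > 1e-8)
    stop_field("window_width", "must divide the temperature span")
  n_win <- round(n_win)
  step <- grid[2] - grid[1]
  per <- window_width / step
  if (abs(per - round(per)) > 1e-8)
    stop_field("window_width", "must be a multiple of the grid step")
  per <- round(per)
  out <- numeric(n_win)
  for (k in seq_len(n_win)) {
    ii <- ((k - 1L) * per + 1L):(k * per + 1L)
    out[k] <- trapz(grid[ii], values[ii])
  }
  names(out) <- as.character(seq_len(n_win))
  out
}

#' Steepest windowed slope and its temperature
#'
#' Over every contiguous window of `points` grid samples, fits a
#' least-squares line and takes the signed maximum slope (steepest rise;
#' ties broken by the lowest temperature). Returns the slope and the centre
#' temperature of the maximizing window — the indices
#' `Max_slope_{p}_S{layer}` and `Tmax_slope_{p}_S{layer}`.
#'
#' @inheritParams total_area
#' @param points window length in samples (3 or 5; any odd value >= 2 works).
#' @return named vector `c(max_slope=, tmax=)`.
#' @export
steepest_slope <- function(grid, values, points = 3L) {
  n <- length(grid)
  if (n < points) stop("curve shorter than the slope window")
  step <- grid[2] - grid[1]
  k <- seq_len(points) - (points + 1) / 2       # centered sample index
  w <- k / (sum(k^2) * step)                    # least-squares slope weights
  n_win <- n - points + 1L
  slopes <- vapply(seq_len(n_win), function(i)
    sum(w * values[i:(i + points - 1L)]), numeric(1))
  # ties (within float jitter) break to the lowest temperature
  m <- max(slopes)
  tol <- 1e-9 * max(abs(m), 1e-12)
  best <- which(slopes >= m - tol)[1]
  centre <- grid[best] + (points - 1) / 2 * step
  c(max_slope = slopes[best], tmax = centre)
}

#' Extract the time-domain index table
#'
#' For each subject and layer: the total area `AS{l}`, the 10 degC and
#' 40 degC subareas `A10S{l}_{k}` / `A40S{l}_{k}`, and the 3- and 5-point
#' steepest slopes with their temperatures. On the default 160 degC span and
#' 3 layers this yields 75 uniquely named indices.
#'
#' @param curves long representative-curves table
#'   ([representative_curves()]).
#' @param subarea_widths window widths for subarea indices, degC.
#' @param slope_points slope window lengths in samples.
#' @return data.frame: `subject_id`, `group`, then one column per index.
#' @export
time_features <- function(curves, subarea_widths = c(10, 40),
                          slope_points = c(3L, 5L)) {
  cm <- curves_matrixify(curves)
  rows <- lapply(seq_len(nrow(cm$labels)), function(i) {
    sid <- cm$labels$subject_id[i]
    feats <- list()
    for (l in cm$layers) {
      v <- cm$value(sid, l)
      feats[[sprintf("AS%d", l)]] <- total_area(cm$grid, v)
      for (w in subarea_widths) {
        sa <- subareas(cm$grid, v, w)
        names(sa) <- sprintf("A%dS%d_%s", w, l, names(sa))
        feats <- c(feats, as.list(sa))
      }
      for (p in slope_points) {
        sl <- steepest_slope(cm$grid, v, p)
        feats[[sprintf("Max_slope_%d_S%d", p, l)]] <- unname(sl["max_slope"])
        feats[[sprintf("Tmax_slope_%d_S%d", p, l)]] <- unname(sl["tmax"])
      }
    }
    feats
  })
  tab <- data.frame(subject_id = cm$labels$subject_id,
                    group = cm$labels$group,
                    do.call(rbind, lapply(rows, function(r)
                      as.data.frame(r, check.names = FALSE))),
                    check.names = FALSE, row.names = NULL)
  validate_feature_table(tab)
  tab
}

# grammar of index names from both domains
index_name_pattern <- paste0(
  "^(AS[0-9]+",
  "|A(10|40)S[0-9]+_[0-9]+",
  "|Max_slope_[35]_S[0-9]+",
  "|Tmax_slope_[35]_S[0-9]+",
  "|W[A-P][1-6]_S[0-9]+)$")

validate_feature_table <- function(tab) {
  idx <- setdiff(names(tab), c("subject_id", "group"))
  if (anyDuplicated(idx)) stop("duplicate index names in feature table")
  bad <- idx[!grepl(index_name_pattern, idx)]
  if (length(bad))
    stop("index name(s) outside the naming grammar: ",
         paste(head(bad, 5), collapse = ", "))
  if (anyNA(tab[idx])) stop("missing values in feature table")
  invisible(tab)
}

#' Read/write feature tables
#'
#' CSV with leading `subject_id`, `group` columns, then one column per named
#' index.
#'
#' @param features feature table (data.frame).
#' @param path CSV file path.
#' @export
write_features <- function(features, path) {
  fwrite_full(features, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  x <- as.data.frame(data.table::fread(path), check.names = FALSE)
  validate_feature_table(x)
  x
}

#' Merge feature tables on subject id
#'
#' @param ... feature tables sharing `subject_id` and `group`.
#' @return merged feature table.
#' @export
merge_features <- function(...) {
  tabs <- list(...)
  out <- Reduce(function(a, b) merge(a, b, by = c("subject_id", "group"),
                                     sort = TRUE), tabs)
  validate_feature_table(out)
  out
}
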