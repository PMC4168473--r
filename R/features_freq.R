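#' Frequency-domain index names
#'
#' The naming grammar `W{letter}{package}_S{layer}`: 16 temperature windows
#' of 10 degC (letters A..P, low to high temperature), 6 scale packages of 5
#' scales each, and the sensor layer. 16 x 6 x 3 = 288 names for 3 layers.
#'
#' @param layers layer indices.
#' @param n_windows number of 10 degC windows.
#' @param n_packages number of 5-scale packages.
#' @return character vector of index names (windows fastest, then package,
#'   then layer).
#' @export
wavelet_index_names <- function(layers = 1:3, n_windows = 16L,
                                n_packages = 6L) {
  if (n_windows > 26L) stop_field("n_windows", "at most 26 (A..Z)")
  unlist(lapply(layers, function(l)
    unlist(lapply(seq_len(n_packages), function(p)
      sprintf("W%s%d_S%d", LETTERS[seq_len(n_windows)], p, l)))))
}

#' Parse a frequency-domain index name
#'
#' @param name index name like `"WA1_S1"`.
#' @return list with `window` (1-based ordinal of the 10 degC window),
#'   `letter`, `package`, `layer`.
#' @export
parse_wavelet_name <- function(name) {
  m <- regmatches(name, regexec("^W([A-P])([1-6])_S([0-9]+)$", name))[[1]]
  if (length(m) != 4L) stop("not a frequency-domain index name: ", name)
  list(window = match(m[2], LETTERS), letter = m[2],
       package = as.integer(m[3]), layer = as.integer(m[4]))
}

#' Summarize a scalogram into scale-package x temperature-window powers
#'
#' Package p covers integer scales `5(p-1)+1 .. 5p`; window k covers
#' relative temperatures `[10(k-1), 10k)` (half-open, so the blocks tile the
#' scale-temperature plane disjointly). The index value is the summed
#' squared coefficient over the block ("summarized power"); set
#' `power = "abs"` for summed absolute coefficients.
#'
#' @param coef scale x temperature coefficient matrix ([cwt_curve()]),
#'   scales 1..max in the rows.
#' @param grid temperatures (degC) of the coefficient columns.
#' @param layer layer index used in the names.
#' @param n_packages,window_width packaging scheme (defaults 6 packages of 5
#'   scales, 10 degC windows).
#' @param power `"squared"` (default) or `"abs"`.
#' @return named vector of `n_windows * n_packages` index values.
#' @export
package_power <- function(coef, grid, layer, n_packages = 6L,
                          window_width = 10, power = c("squared", "abs")) {
  power <- match.arg(power)
  scales_per <- 5L
  if (nrow(coef) < n_packages * scales_per)
    stop_field("coef", sprintf("needs at least %d scales",
                               n_packages * scales_per))
  rel <- grid - grid[1]
  span <- rel[length(rel)]
  n_windows <- floor(span / window_width)
  if (n_windows < 1L) stop_field("grid", "span shorter than one window")
  win_id <- floor(rel / window_width) + 1L   # half-open: top edge excluded
  p2 <- if (power == "squared") coef^2 else abs(coef)
  out <- numeric(n_windows * n_packages)
  nm <- character(length(out))
  i <- 0L
  for (p in seq_len(n_packages)) {
    srows <- ((p - 1L) * scales_per + 1L):(p * scales_per)
    for (k in seq_len(n_windows)) {
      cols <- which(win_id == k)
      i <- i + 1L
      out[i] <- sum(p2[srows, cols])
      nm[i] <- sprintf("W%s%d_S%d", LETTERS[k], p, layer)
    }
  }
  names(out) <- nm
  out
}

#' Extract the frequency-domain index table
#'
#' Continuous Daubechies wavelet transform of each representative curve
#' (scales 1..30), summarized into 6 scale packages x 16 temperature windows
#' per layer: 288 indices for the default 3-layer, 160 degC design.
#'
#' @inheritParams time_features
#' @param wavelet mother wavelet, default `"db4"`.
#' @param max_scale largest integer scale, default 30.
#' @param power see [package_power()].
#' @return data.frame: `subject_id`, `group`, then one column per index.
#' @export
freq_features <- function(curves, wavelet = "db4", max_scale = 30L,
                          power = c("squared", "abs")) {
  power <- match.arg(power)
  cm <- curves_matrixify(curves)
  n_packages <- max_scale %/% 5L
  rows <- lapply(seq_len(nrow(cm$labels)), function(i) {
    sid <- cm$labels$subject_id[i]
    unlist(lapply(cm$layers, function(l) {
      v <- cm$value(sid, l)
      coef <- cwt_curve(v, scales = seq_len(max_scale), wavelet = wavelet)
      package_power(coef, cm$grid, l, n_packages = n_packages,
                    power = power)
    }))
  })
  tab <- data.frame(subject_id = cm$labels$subject_id,
                    group = cm$labels$group,
                    do.call(rbind, rows),
                    check.names = FALSE, row.names = NULL)
  validate_feature_table(tab)
  tab
}
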