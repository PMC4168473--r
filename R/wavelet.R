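# Daubechies filters and a continuous wavelet transform on equidistant
# curves. No CWT package ships with the runtime, so the transform is built
# from first principles: orthonormal scaling filter by spectral
# factorization, wavelet function by the cascade (inverse-transform)
# iteration, CWT by convolution with the integrated, rescaled wavelet
# followed by differencing.

poly_mult <- function(a, b) {
  out <- rep(0 + 0i, length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  out
}

#' Daubechies scaling filter coefficients
#'
#' Computes the orthonormal Daubechies scaling (low-pass) filter of a given
#' order (number of vanishing moments) by spectral factorization: the
#' binomial polynomial roots are found with [polyroot()] and the minimum-
#' phase factor (roots inside the unit circle) is retained. `order = 4`
#' reproduces the classic db4 8-tap filter.
#'
#' @param order number of vanishing moments (db`order`), >= 1.
#' @return numeric vector of length `2 * order`, summing to `sqrt(2)`.
#' @export
daubechies_filter <- function(order) {
  order <- as.integer(order)
  if (order < 1L) stop_field("order", "must be >= 1")
  if (order == 1L) return(c(1, 1) / sqrt(2))
  N <- order
  k <- 0:(N - 1L)
  Pcoef <- choose(N - 1L + k, k)            # P(y), ascending powers
  yroots <- polyroot(Pcoef)
  zroots <- vapply(yroots, function(y0) {
    b <- 2 - 4 * y0                          # z^2 - (2-4y) z + 1 = 0
    disc <- sqrt(b^2 - 4 + 0i)
    z1 <- (b + disc) / 2
    z2 <- (b - disc) / 2
    if (Mod(z1) < 1) z1 else z2
  }, complex(1))
  coefs <- 1 + 0i
  for (r in c(rep(-1 + 0i, N), zroots)) coefs <- poly_mult(coefs, c(1, -r))
  h <- Re(coefs)
  h * sqrt(2) / sum(h)
}

qmf_filter <- function(h) {
  L <- length(h)
  rev(h) * (-1)^(seq_len(L) - 1L)
}

upsample2 <- function(x) {
  out <- numeric(2L * length(x) - 1L)
  out[seq(1L, length(out), by = 2L)] <- x
  out
}

conv_full <- function(x, f) {
  n <- length(x) + length(f) - 1L
  nf <- stats::nextn(n, 2)
  Re(stats::fft(stats::fft(c(x, numeric(nf - length(x)))) *
                stats::fft(c(f, numeric(nf - length(f)))),
                inverse = TRUE))[seq_len(n)] / nf
}

#' Approximate a Daubechies wavelet function on a dyadic grid
#'
#' Cascade approximation of the mother wavelet psi via iterated inverse
#' transform of a unit detail coefficient.
#'
#' @param order Daubechies order.
#' @param level number of refinement iterations (grid resolution `2^-level`).
#' @return list with `x` (support `[0, 2*order-1]`) and `psi` values.
#' @export
wavelet_function <- function(order, level = 10L) {
  h <- daubechies_filter(order)
  g <- qmf_filter(h)
  rec <- g
  if (level > 1L) for (l in 2:level) rec <- conv_full(upsample2(rec), h)
  psi <- 2^(level / 2) * rec
  list(x = seq(0, 2 * order - 1, length.out = length(psi)), psi = psi)
}

wavelet_cache <- new.env(parent = emptyenv())

parse_wavelet <- function(wavelet) {
  m <- regmatches(wavelet, regexec("^db([0-9]+)$", wavelet))[[1]]
  if (length(m) != 2L)
    stop_field("wavelet", sprintf(
      "unknown wavelet '%s'; use 'db<order>' (e.g. 'db4')", wavelet))
  as.integer(m[2])
}

int_psi_for <- function(wavelet, level = 10L) {
  key <- paste0(wavelet, "_", level)
  if (!is.null(wavelet_cache[[key]])) return(wavelet_cache[[key]])
  order <- parse_wavelet(wavelet)
  wf <- wavelet_function(order, level)
  dx <- wf$x[2] - wf$x[1]
  res <- list(int_psi = cumsum(wf$psi) * dx, dx = dx,
              support = 2 * order - 1)
  wavelet_cache[[key]] <- res
  res
}

# symmetric (half-point reflection) extension index for i in 1..anything
sym_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

#' Continuous wavelet transform of a representative curve
#'
#' Correlates the curve with integer-scale dilations of a Daubechies wavelet
#' (coefficients computed as the differenced convolution with the integrated,
#' rescaled wavelet). The signal is symmetrically extended at the
#' boundaries, so a constant input yields exactly zero coefficients at every
#' scale.
#'
#' @param values conductance on an equidistant grid.
#' @param scales integer scales (grid-sample units), default `1:30`.
#' @param wavelet mother wavelet name, `"db<order>"`; default `"db4"`.
#' @return matrix `length(scales) x length(values)` of coefficients, with
#'   `scales` as `rownames`.
#' @export
cwt_curve <- function(values, scales = 1:30, wavelet = "db4") {
  if (any(scales < 1)) stop_field("scales", "must be >= 1")
  ip <- int_psi_for(wavelet)
  n <- length(values)
  out <- matrix(0, nrow = length(scales), ncol = n)
  rownames(out) <- as.character(scales)
  for (si in seq_along(scales)) {
    s <- scales[si]
    j <- floor(seq(0, s * ip$support, by = 1) / (s * ip$dx)) + 1L
    j <- j[j <= length(ip$int_psi)]
    filt <- rev(ip$int_psi[j])
    L <- length(filt)
    pad <- L
    ext <- values[sym_index((1L - pad):(n + pad), n)]
    cv <- conv_full(ext, filt)
    coef <- -sqrt(s) * diff(cv)
    m <- length(coef)
    keep_len <- n + 2L * pad
    d <- (m - keep_len) / 2
    centre <- coef[(floor(d) + 1L):(m - ceiling(d))]
    out[si, ] <- centre[(pad + 1L):(pad + n)]
  }
  out
}
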