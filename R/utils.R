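#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not disturb the global RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# trapezoidal integral of y over x
trapz <- function(x, y) {
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

# CSV writer that preserves doubles bit-exactly (17 significant digits
# round-trip through strtod); fwrite's default 15 digits does not.
fwrite_full <- function(x, path) {
  x <- data.table::as.data.table(x)
  for (j in names(x)) {
    if (is.double(x[[j]])) data.table::set(x, j = j,
                                           value = sprintf("%.17g", x[[j]]))
  }
  data.table::fwrite(x, path)
  invisible(path)
}
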