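#' Round half away from zero
#'
#' Decimal rounding with the "round half up" convention used in the report
#' tables (base [round()] rounds half to even). `round_half_up(2.675, 1)` is
#' 2.7, not 2.6.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1, the table convention).
#' @return Numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(c(16.666667, 28.333333))
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## internal argument checks ---------------------------------------------------

stop_borondose <- function(msg, class, call. = FALSE, ...) {
  cnd <- structure(
    class = c(class, "borondose_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1), ...)
  )
  stop(cnd)
}

check_number <- function(x, name, min = -Inf, allow_na = FALSE) {
  if (allow_na && length(x) == 1L && is.na(x)) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_borondose(sprintf("'%s' must be a single finite number", name),
                   "borondose_validation_error")
  }
  if (x < min) {
    stop_borondose(sprintf("'%s' must be >= %g (got %g)", name, min, x),
                   "borondose_validation_error")
  }
  invisible(x)
}

check_numeric_vec <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop_borondose(sprintf("'%s' must be a finite numeric vector", name),
                   "borondose_validation_error")
  }
  if (any(x < min)) {
    stop_borondose(sprintf("all elements of '%s' must be >= %g", name, min),
                   "borondose_validation_error")
  }
  invisible(x)
}

## run code under a fixed seed without disturbing the caller's RNG stream
with_preserved_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

## piecewise-linear interpolation that extrapolates with the boundary slopes;
## the in vitro time -> dose ladder needs this beyond the last rung
interp_extrap <- function(x, y, xout) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  o <- order(x); x <- x[o]; y <- y[o]
  n <- length(x)
  out <- stats::approx(x, y, xout, rule = 2)$y
  lo <- xout < x[1L]
  hi <- xout > x[n]
  if (any(lo)) out[lo] <- y[1L] + (xout[lo] - x[1L]) * (y[2L] - y[1L]) / (x[2L] - x[1L])
  if (any(hi)) out[hi] <- y[n] + (xout[hi] - x[n]) * (y[n] - y[n - 1L]) / (x[n] - x[n - 1L])
  out
}
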