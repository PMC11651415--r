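#' Piecewise-linear parameter tables (AFGEN)
#'
#' WOFOST-style crop parameters that vary with development stage (DVS) or
#' temperature are stored as breakpoint tables and evaluated by linear
#' interpolation, clamped to the first/last ordinate outside the breakpoint
#' range.
#'
#' @param x Numeric vector of abscissae (DVS, dimensionless, or temperature
#'   in degrees C), strictly increasing, length >= 2.
#' @param y Numeric vector of ordinates, same length as \code{x}.
#' @return An object of class \code{afgen}.
#' @examples
#' slatb <- afgen(c(0, 2), c(0.0022, 0.0018))
#' afgen_eval(slatb, 1)     # midpoint
#' afgen_eval(slatb, -1)    # clamped to first ordinate
#' @export
afgen <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(x) != length(y))
    stop("afgen table needs >= 2 (x, y) pairs of equal length", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("afgen table values must be finite", call. = FALSE)
  if (any(diff(x) <= 0))
    stop("afgen abscissae must be strictly increasing", call. = FALSE)
  structure(list(x = x, y = y), class = "afgen")
}

#' @rdname afgen
#' @param table An \code{afgen} table.
#' @param at Numeric vector of points at which to evaluate the table.
#' @export
afgen_eval <- function(table, at) {
  x <- table$x; y <- table$y
  n <- length(x)
  if (length(at) == 1L) {  # fast scalar path used in the daily loop
    if (at <= x[1L]) return(y[1L])
    if (at >= x[n]) return(y[n])
    i <- findInterval(at, x)
    return(y[i] + (y[i + 1L] - y[i]) * (at - x[i]) / (x[i + 1L] - x[i]))
  }
  stats::approx(x, y, xout = at, rule = 2, ties = "ordered")$y
}

#' @export
print.afgen <- function(x, ...) {
  cat("AFGEN table (", length(x$x), " breakpoints)\n", sep = "")
  print(rbind(x = x$x, y = x$y))
  invisible(x)
}

is_afgen <- function(x) inherits(x, "afgen")

afgen_eval_vec <- function(table, at)
  stats::approx(table$x, table$y, xout = at, rule = 2, ties = "ordered")$y

# Fast closure used inside the engine's daily loop: one approxfun per table.
afgen_fun <- function(table) {
  stats::approxfun(table$x, table$y, rule = 2, ties = "ordered")
}
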