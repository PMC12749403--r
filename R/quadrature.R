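#' Composite Boole (Newton--Cotes 5-point) integration
#'
#' Integrates regularly sampled values with the closed Newton--Cotes rule on
#' five points (Boole's rule), applied over consecutive panels of four
#' intervals. The rule is exact for polynomials up to degree five. A remainder
#' of one to three trailing intervals is integrated with Simpson's rule (two
#' intervals) and/or the trapezoid rule, so any number of samples >= 2 is
#' accepted.
#'
#' @param y Numeric vector of samples on a regular grid.
#' @param dx Grid spacing (same unit as the desired integral's abscissa).
#' @return The integral as a single number.
#' @examples
#' x <- seq(0, 1, length.out = 101)
#' boole_integral(x^4, dx = x[2] - x[1]) # 1/5, to machine precision
#' @export
boole_integral <- function(y, dx) {
  stopifnot(is.numeric(y), length(y) >= 2, is.numeric(dx), dx > 0)
  n_int <- length(y) - 1L
  n_pan <- n_int %/% 4L
  total <- 0
  if (n_pan > 0L) {
    idx <- seq_len(n_pan * 4L + 1L)
    total <- total + boole_panels(y[idx], dx)
  }
  rem <- n_int - n_pan * 4L
  if (rem > 0L) {
    yr <- y[(n_pan * 4L + 1L):length(y)]
    total <- total + small_rule(yr, dx)
  }
  total
}

# Sum of Boole panels; length(y) = 4k + 1.
boole_panels <- function(y, dx) {
  n_pan <- (length(y) - 1L) %/% 4L
  i0 <- (seq_len(n_pan) - 1L) * 4L + 1L
  s <- 7 * (y[i0] + y[i0 + 4L]) + 32 * (y[i0 + 1L] + y[i0 + 3L]) + 12 * y[i0 + 2L]
  sum(s) * 2 * dx / 45
}

# 1-3 interval remainder: Simpson on pairs, trapezoid on a lone interval.
small_rule <- function(y, dx) {
  n_int <- length(y) - 1L
  if (n_int == 0L) return(0)
  if (n_int == 1L) return((y[1] + y[2]) * dx / 2)
  if (n_int == 2L) return((y[1] + 4 * y[2] + y[3]) * dx / 3)
  (y[1] + 4 * y[2] + y[3]) * dx / 3 + (y[3] + y[4]) * dx / 2
}

#' Cumulative Boole integral on a regular grid
#'
#' Running integral of `y` from the first sample to every sample, using full
#' Boole panels where available and Simpson/trapezoid closures for
#' intermediate points, so the cumulative value at panel boundaries matches
#' [boole_integral()] exactly.
#'
#' @inheritParams boole_integral
#' @return Numeric vector of the same length as `y`; first element 0.
#' @export
cum_boole <- function(y, dx) {
  stopifnot(is.numeric(y), length(y) >= 1, dx > 0)
  n <- length(y)
  out <- numeric(n)
  if (n == 1L) return(out)
  n_pan <- (n - 1L) %/% 4L
  # cumulative integral at panel boundaries 1, 5, 9, ... (cpan[m] = up to 4m+1)
  cpan <- 0
  if (n_pan > 0L) {
    i0 <- (seq_len(n_pan) - 1L) * 4L + 1L
    pans <- (7 * (y[i0] + y[i0 + 4L]) + 32 * (y[i0 + 1L] + y[i0 + 3L]) +
               12 * y[i0 + 2L]) * 2 * dx / 45
    cpan <- c(0, cumsum(pans))
  }
  for (k in 2:n) {
    m <- (k - 1L) %/% 4L   # complete panels before sample k
    pos <- (k - 1L) %% 4L
    if (pos == 0L) {
      out[k] <- cpan[m + 1L]
    } else {
      i <- m * 4L + 1L     # last boundary at or before k
      out[k] <- cpan[m + 1L] + small_rule(y[i:k], dx)
    }
  }
  out
}

#' Tenfold (or other) spline upsampling of a regular time series
#'
#' Cubic-spline interpolation onto a grid `factor` times finer, used before
#' Boole integration and peak refinement. Natural end conditions keep the
#' interpolant from oscillating at the record edges.
#'
#' @param t Time stamps (regular grid).
#' @param y Values.
#' @param factor Integer upsampling factor (default 10).
#' @return List with `t` and `y` on the fine grid (original samples are a
#'   subset of the fine grid).
#' @export
upsample_spline <- function(t, y, factor = 10L) {
  stopifnot(length(t) == length(y), length(t) >= 2, factor >= 1)
  n_fine <- (length(t) - 1L) * as.integer(factor) + 1L
  sp <- stats::spline(t, y, n = n_fine, method = "natural")
  list(t = sp$x, y = sp$y)
}
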