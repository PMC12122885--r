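#' Uniformly sampled scalar time series
#'
#' Light container for uniformly sampled signals (steering angle, steering
#' rate, stimulus cues). Stored as a start time, a sample interval and a
#' finite value vector.
#'
#' @param values numeric vector of samples; must be finite and non-empty.
#' @param dt sample interval in seconds, `> 0`.
#' @param t0 time of the first sample in seconds.
#' @return an object of class `sf_signal`.
#' @examples
#' s <- new_signal(sin(seq(0, 2 * pi, length.out = 90)), dt = 1 / 90)
#' range(signal_time(s))
#' @export
new_signal <- function(values, dt, t0 = 0) {
  values <- as.numeric(values)
  stopifnot(is.numeric(dt), length(dt) == 1L, is.finite(dt), dt > 0,
            length(t0) == 1L, is.finite(t0), length(values) >= 1L)
  if (!all(is.finite(values))) stop("signal values must be finite")
  structure(list(t0 = as.numeric(t0), dt = as.numeric(dt), values = values),
            class = "sf_signal")
}

#' Sample times of a signal
#'
#' @param x an `sf_signal`.
#' @return numeric vector `t0 + dt * (0 ... n-1)`.
#' @export
signal_time <- function(x) {
  stopifnot(inherits(x, "sf_signal"))
  x$t0 + x$dt * (seq_along(x$values) - 1)
}

#' @export
print.sf_signal <- function(x, ...) {
  cat(sprintf("<sf_signal> n=%d dt=%.6gs span=[%.4g, %.4g]s\n",
              length(x$values), x$dt, x$t0,
              x$t0 + x$dt * (length(x$values) - 1)))
  invisible(x)
}

#' @export
as.data.frame.sf_signal <- function(x, ...) {
  data.frame(t = signal_time(x), value = x$values)
}

#' Linear interpolation of a signal at arbitrary times
#'
#' Times outside the sampled span, or spanning non-finite neighbours, give
#' `NA`.
#'
#' @param x an `sf_signal`.
#' @param t times in seconds.
#' @return numeric vector, `NA` where undefined.
#' @export
signal_at <- function(x, t) {
  stopifnot(inherits(x, "sf_signal"))
  tt <- signal_time(x)
  if (length(x$values) == 1L) {
    return(ifelse(abs(t - tt) < .Machine$double.eps * 8, x$values, NA_real_))
  }
  approx(tt, x$values, xout = t, method = "linear", rule = 1)$y
}
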