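#' Wrap angles to (-pi, pi]
#'
#' @param x angles in radians.
#' @return wrapped angles in `(-pi, pi]`.
#' @examples
#' wrap_angle(-6.2)  # ~ 0.0832
#' @export
wrap_angle <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  # %% puts exact odd multiples of pi at -pi; the convention here is (-pi, pi]
  w[w <= -pi] <- pi
  w
}

#' Circular mean direction
#'
#' Mean direction of a set of angles, `arg(sum(exp(i * theta)))`. The mean
#' is undefined when the resultant vector is (numerically) zero, e.g. for
#' antipodal pairs `{0, pi}`.
#'
#' @param angles angles in radians; non-finite entries are an error.
#' @param eps undefined-mean guard: an error is raised when the resultant
#'   length is below `eps * length(angles)`.
#' @return mean angle in `(-pi, pi]`.
#' @examples
#' circular_mean_angle(c(3, -3))  # pi, not the arithmetic mean 0
#' @export
circular_mean_angle <- function(angles, eps = 1e-9) {
  angles <- as.numeric(angles)
  if (length(angles) == 0L) stop("empty angle set")
  if (!all(is.finite(angles))) stop("angles must be finite")
  s <- sum(sin(angles))
  c_ <- sum(cos(angles))
  if (sqrt(s^2 + c_^2) < eps * length(angles)) {
    stop("undefined circular mean: resultant length ~ 0")
  }
  atan2(s, c_)
}

#' Circular median direction
#'
#' The sample angle minimizing the summed absolute circular deviation to all
#' other samples (the natural generalization of the median to a cyclic
#' quantity; computed exhaustively, O(n^2)).
#'
#' @param angles angles in radians.
#' @return median angle in `(-pi, pi]`, one of the input angles (wrapped).
#' @export
circular_median_angle <- function(angles) {
  angles <- wrap_angle(as.numeric(angles))
  if (length(angles) == 0L) stop("empty angle set")
  if (!all(is.finite(angles))) stop("angles must be finite")
  if (length(angles) == 1L) return(angles)
  dev <- vapply(angles, function(a) sum(abs(wrap_angle(angles - a))), 0)
  angles[which.min(dev)]
}
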