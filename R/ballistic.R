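#' Gaussian ballistic steering corrections
#'
#' A single rapid aimed steering sub-movement is modelled with a symmetric
#' Gaussian velocity profile
#' \deqn{\dot\delta_b(t) = a_I \exp(-(t-\mu_I)^2 / (2\sigma_I^2))}
#' parameterized by a signed strength `a` (rad/s), a mode time `mu` (s) and
#' a rate parameter `sigma` (s). Complex movements are superpositions of
#' such corrections. A correction set is a data frame with one row per
#' correction, kept sorted by mode time (ties broken by larger `|a|`
#' first so serialization is deterministic).
#'
#' @param a correction strength(s), radians/second (signed).
#' @param mu correction mode time(s), seconds.
#' @param sigma correction rate parameter(s), seconds, `> 0`.
#' @return an `sf_corrections` data frame with columns `a`, `mu`, `sigma`.
#' @examples
#' cs <- correction_set(a = c(1, -0.5), mu = c(0.8, 1.1), sigma = c(0.1, 0.08))
#' travel_distance(cs)
#' @export
correction_set <- function(a = numeric(), mu = numeric(), sigma = numeric()) {
  a <- as.numeric(a); mu <- as.numeric(mu); sigma <- as.numeric(sigma)
  n <- length(a)
  stopifnot(length(mu) == n, length(sigma) == n)
  if (n > 0) {
    if (!all(is.finite(a), is.finite(mu), is.finite(sigma)))
      stop("correction parameters must be finite")
    if (any(sigma <= 0)) stop("sigma must be > 0")
  }
  ord <- order(mu, -abs(a))
  structure(data.frame(a = a[ord], mu = mu[ord], sigma = sigma[ord]),
            class = c("sf_corrections", "data.frame"))
}

#' @rdname correction_set
#' @export
ballistic_correction <- function(a, mu, sigma) {
  stopifnot(length(a) == 1L, length(mu) == 1L, length(sigma) == 1L)
  correction_set(a, mu, sigma)
}

as_one_correction <- function(c) {
  if (inherits(c, "sf_corrections")) {
    if (nrow(c) != 1L) stop("expected exactly one correction")
    return(list(a = c$a, mu = c$mu, sigma = c$sigma))
  }
  stopifnot(is.list(c), all(c("a", "mu", "sigma") %in% names(c)))
  c
}

erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

#' Velocity profile of one ballistic correction
#'
#' @param t time(s), seconds; vectorized.
#' @param c a one-row [correction_set()] (or a list with `a`, `mu`, `sigma`).
#' @return steering rate in radians/second at `t`.
#' @export
correction_velocity <- function(t, c) {
  c <- as_one_correction(c)
  if (!all(is.finite(t))) stop("non-finite time")
  c$a * exp(-(t - c$mu)^2 / (2 * c$sigma^2))
}

#' Superpose a correction set on a time grid
#'
#' Pointwise sum of the velocity profiles of all corrections in the set; the
#' resulting complex movement rate follows the principle of superposition.
#'
#' @param set an `sf_corrections` set.
#' @param grid an `sf_signal` (its values are ignored, only the time grid is
#'   used) or a numeric vector of times.
#' @return an `sf_signal` on the same grid when `grid` is a signal, else a
#'   numeric vector.
#' @export
superpose <- function(set, grid) {
  stopifnot(inherits(set, "sf_corrections"))
  tt <- if (inherits(grid, "sf_signal")) signal_time(grid) else as.numeric(grid)
  v <- superpose_eval_cpp(tt, set$a, set$mu, set$sigma)
  if (inherits(grid, "sf_signal")) new_signal(v, dt = grid$dt, t0 = grid$t0) else v
}

#' Onset and offset times of a correction
#'
#' Defined as `mu -/+ 2 sigma`; the enclosed duration `4 sigma` covers
#' approximately 95.4 % of the theoretical movement.
#'
#' @inheritParams correction_velocity
#' @return named numeric `c(on, off)` (for a set: a two-column matrix).
#' @export
onset_offset <- function(c) {
  if (inherits(c, "sf_corrections") && nrow(c) != 1L) {
    return(cbind(on = c$mu - 2 * c$sigma, off = c$mu + 2 * c$sigma))
  }
  c <- as_one_correction(c)
  c(on = c$mu - 2 * c$sigma, off = c$mu + 2 * c$sigma)
}

#' Position profile of one ballistic correction
#'
#' Primitive function of the Gaussian velocity profile,
#' `a * sigma * sqrt(pi/2) * erf((t - mu) / (sqrt(2) * sigma)) + C`.
#'
#' @inheritParams correction_velocity
#' @param C integration constant (position at the mode), radians.
#' @return steering angle in radians at `t`.
#' @export
correction_position <- function(t, c, C = 0) {
  c <- as_one_correction(c)
  c$a * c$sigma * sqrt(pi / 2) * erf((t - c$mu) / (sqrt(2) * c$sigma)) + C
}

#' Full travel distance of ballistic corrections
#'
#' Net steering-angle change of each correction, `a * sigma * sqrt(2*pi)`
#' (the integral of the velocity profile over the whole real line).
#'
#' @param c a correction set (any number of rows) or a single correction.
#' @return numeric vector of travel distances in radians, one per correction.
#' @export
travel_distance <- function(c) {
  if (inherits(c, "sf_corrections")) return(c$a * c$sigma * sqrt(2 * pi))
  c <- as_one_correction(c)
  c$a * c$sigma * sqrt(2 * pi)
}

#' Movement fraction enclosed by mu +/- k sigma
#'
#' Fraction of the total absolute velocity integral of one correction lying
#' within `k` rate parameters of the mode; equals `erf(k / sqrt(2))`.
#' `coverage_fraction(2)` is approximately 0.954.
#'
#' @param k half-width in units of sigma, `> 0`.
#' @return fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(k) {
  if (any(!is.na(k) & k <= 0)) stop("k must be > 0")
  erf(k / sqrt(2))
}

#' Read / write correction sets as CSV
#'
#' Columns `a` (rad/s), `mu` (s), `sigma` (s) plus derived convenience
#' columns `t_on`, `t_off` (s) and `delta` (rad, the travel distance);
#' derived columns are recomputed on read and ignored if present.
#'
#' @param set an `sf_corrections` set.
#' @param path file path.
#' @return `read_corrections` returns an `sf_corrections` set.
#' @export
write_corrections <- function(set, path) {
  stopifnot(inherits(set, "sf_corrections"))
  oo <- onset_offset(set)
  if (nrow(set) == 1L) oo <- matrix(oo, nrow = 1, dimnames = list(NULL, c("on", "off")))
  df <- data.frame(a = set$a, mu = set$mu, sigma = set$sigma,
                   t_on = if (nrow(set)) oo[, "on"] else numeric(),
                   t_off = if (nrow(set)) oo[, "off"] else numeric(),
                   delta = travel_distance(set))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_corrections
#' @export
read_corrections <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("a", "mu", "sigma") %in% names(df)))
  correction_set(df$a, df$mu, df$sigma)
}
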