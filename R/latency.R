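#' Pair ballistic corrections with a lagged stimulus cue
#'
#' For each correction, the response is its travel distance and the
#' stimulus is the cue signal linearly interpolated at `t_on - tau`, where
#' `t_on` is the correction onset. Pairs whose lagged stimulus sample is
#' unavailable (outside the cue span or `NA`) are dropped.
#'
#' @param set an `sf_corrections` set (or a list of sets; pairs are pooled).
#' @param cue stimulus `sf_signal` (or a list parallel to `set`).
#' @param tau candidate response time, seconds.
#' @param onset_def onset definition: `"2sigma"` (`mu - 2 sigma`, default),
#'   `"1sigma"` or `"mode"`.
#' @return an `sf_pairs` data frame with columns `response` (rad) and
#'   `stimulus` (cue units), attribute `tau`.
#' @export
pair_corrections_with_stimulus <- function(set, cue, tau,
                                           onset_def = c("2sigma", "1sigma",
                                                         "mode")) {
  onset_def <- match.arg(onset_def)
  sets <- if (inherits(set, "sf_corrections")) list(set) else set
  cues <- if (inherits(cue, "sf_signal")) list(cue) else cue
  stopifnot(length(sets) == length(cues))
  k <- switch(onset_def, "2sigma" = 2, "1sigma" = 1, "mode" = 0)
  resp <- numeric(); stim <- numeric()
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    if (nrow(s) == 0) next
    t_on <- s$mu - k * s$sigma
    v <- signal_at(cues[[i]], t_on - tau)
    ok <- is.finite(v)
    resp <- c(resp, travel_distance(s)[ok])
    stim <- c(stim, v[ok])
  }
  if (length(resp) == 0) stop("all stimulus-response pairs dropped")
  structure(data.frame(response = resp, stimulus = stim),
            class = c("sf_pairs", "data.frame"), tau = tau)
}

#' Zero-normalized cross-correlation of paired responses and stimuli
#'
#' The Pearson correlation coefficient of the (response, stimulus) pairs;
#' bringing both sides to zero mean and unit scale bounds it in `[-1, 1]`.
#'
#' @param pairs an `sf_pairs` data frame (>= 3 rows, both sides
#'   non-constant).
#' @return correlation in `[-1, 1]`.
#' @export
zncc <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("response", "stimulus") %in% names(pairs)))
  if (nrow(pairs) < 3) stop("need at least 3 pairs")
  if (sd(pairs$response) == 0 || sd(pairs$stimulus) == 0) {
    stop("undefined correlation: constant side")
  }
  cor(pairs$response, pairs$stimulus)
}

scan_engine <- function(set, cue, grid_step, tau_range, onset_def, stat) {
  stopifnot(grid_step > 0)
  tau_grid <- seq(tau_range[1], tau_range[2], by = grid_step)
  rho <- vapply(tau_grid, function(tau) {
    tryCatch({
      p <- pair_corrections_with_stimulus(set, cue, tau, onset_def)
      if (nrow(p) < 3 || sd(p$response) == 0 || sd(p$stimulus) == 0) {
        NA_real_
      } else {
        stat(p$response, p$stimulus)
      }
    }, error = function(e) NA_real_)
  }, 0)
  tau_star <- if (all(is.na(rho))) NA_real_ else tau_grid[which.max(rho)]
  structure(list(tau_grid = tau_grid, rho = rho, tau_star = tau_star),
            class = "sf_latency_scan")
}

#' Response-time scan by cross-correlation maximization
#'
#' Evaluates the zero-normalized cross-correlation between per-correction
#' travel angles and the lagged stimulus cue over a grid of candidate
#' response times, and returns the lag maximizing it (ties resolve to the
#' smallest lag; undefined lags are excluded from the argmax).
#'
#' @inheritParams pair_corrections_with_stimulus
#' @param grid_step lag grid step, seconds (default one 90 Hz sample).
#' @param tau_range scanned lag interval, seconds.
#' @return an `sf_latency_scan` list: `tau_grid`, `rho`, `tau_star`.
#' @export
latency_scan <- function(set, cue, grid_step = 1 / 90, tau_range = c(0, 2),
                         onset_def = "2sigma") {
  scan_engine(set, cue, grid_step, tau_range, onset_def,
              function(r, s) cor(r, s))
}

#' @rdname latency_scan
#' @param method rank statistic: `"spearman"` or `"kendall"`.
#' @export
rank_correlation_scan <- function(set, cue, grid_step = 1 / 90,
                                  tau_range = c(0, 2),
                                  method = c("spearman", "kendall"),
                                  onset_def = "2sigma") {
  method <- match.arg(method)
  scan_engine(set, cue, grid_step, tau_range, onset_def,
              function(r, s) cor(r, s, method = method))
}

#' @export
print.sf_latency_scan <- function(x, ...) {
  cat(sprintf("<sf_latency_scan> %d lags in [%.3g, %.3g]s, tau* = %.4gs (rho = %.3g)\n",
              length(x$tau_grid), min(x$tau_grid), max(x$tau_grid),
              x$tau_star, max(x$rho, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.sf_latency_scan <- function(x, ...) {
  graphics::plot(x$tau_grid, x$rho, type = "l", xlab = "response time (s)",
                 ylab = "correlation", ...)
  graphics::abline(v = x$tau_star, lty = 2)
  invisible(x)
}

#' Recenter an angle series per curve bend
#'
#' Subtracts the circular mean of each curve's valid samples from that
#' curve's samples, so left and right bends are centered around zero
#' independently.
#'
#' @param series an `sf_rof_series`.
#' @param labels per-sample section labels; samples labelled
#'   `"left_curve"` / `"right_curve"` are recentered, others pass through.
#' @return the recentered series; per-curve means in `attr(, "centers")`.
#' @export
recenter_by_curve <- function(series, labels) {
  stopifnot(inherits(series, "sf_rof_series"), length(labels) == nrow(series))
  out <- series
  centers <- list()
  for (lab in c("left_curve", "right_curve")) {
    sel <- labels == lab & series$valid
    if (!any(sel)) stop(sprintf("no valid samples for %s", lab))
    m <- circular_mean_angle(series$angle[sel])
    out$angle[sel] <- wrap_angle(series$angle[sel] - m)
    centers[[lab]] <- m
  }
  attr(out, "centers") <- centers
  out
}

#' Robust linear regression with the pseudo-Huber loss
#'
#' Minimizes `sum(delta^2 * (sqrt(1 + (r/delta)^2) - 1))` over slope and
#' intercept; quadratic for small residuals, linear for gross outliers.
#' Deterministic (BFGS from the least-squares start).
#'
#' @param pairs an `sf_pairs` data frame (stimulus = x, response = y), or
#'   any data frame with those columns.
#' @param huber_delta loss transition scale; `Inf` reproduces least
#'   squares.
#' @return list with `slope`, `intercept`, `huber_delta`.
#' @export
robust_linreg <- function(pairs, huber_delta = 1) {
  stopifnot(all(c("response", "stimulus") %in% names(pairs)),
            nrow(pairs) >= 3, huber_delta > 0)
  x <- pairs$stimulus; y <- pairs$response
  if (sd(x) == 0) stop("degenerate regression: all stimuli equal")
  ls <- stats::lm.fit(cbind(1, x), y)$coefficients
  if (!is.finite(huber_delta)) {
    return(list(slope = unname(ls[2]), intercept = unname(ls[1]),
                huber_delta = huber_delta))
  }
  loss <- function(p) {
    r <- y - p[1] - p[2] * x
    sum(huber_delta^2 * (sqrt(1 + (r / huber_delta)^2) - 1))
  }
  o <- optim(c(ls[1], ls[2]), loss, method = "BFGS",
             control = list(maxit = 500, reltol = 1e-14))
  list(slope = unname(o$par[2]), intercept = unname(o$par[1]),
       huber_delta = huber_delta)
}
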