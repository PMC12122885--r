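#' Response-latency components
#'
#' Total stimulus-to-movement-onset delay decomposed into perception,
#' control decision and muscular activation delays; `tau_d` is their sum.
#'
#' @param tau_p perception delay, seconds.
#' @param tau_c control decision delay, seconds (0 for purely
#'   stimulus-triggered responses).
#' @param tau_m muscular activation delay, seconds.
#' @return an `sf_latency` list with `tau_p`, `tau_c`, `tau_m`, `tau_d`.
#' @export
latency_components <- function(tau_p = 0.1, tau_c = 0, tau_m = 0.05) {
  stopifnot(tau_p >= 0, tau_c >= 0, tau_m >= 0)
  structure(list(tau_p = tau_p, tau_c = tau_c, tau_m = tau_m,
                 tau_d = tau_p + tau_c + tau_m),
            class = "sf_latency")
}

#' Intermittent-driver parameters
#'
#' The synthetic driver perceives a weighted error of heading deviation and
#' lateral lane displacement, accumulates it in a leaky evidence integrator
#' and, on threshold crossing, schedules one Gaussian ballistic steering
#' correction whose onset lags the trigger by the injected response time
#' `latency$tau_d` and whose travel distance is proportional to the error
#' at the trigger.
#'
#' @param error_threshold evidence threshold triggering a correction
#'   (radian-scaled error units).
#' @param evidence_gain evidence accumulation gain, 1/seconds.
#' @param leak evidence leak rate, 1/seconds.
#' @param latency an [latency_components()] (injected response time).
#' @param amplitude_gain steering travel (rad at the wheel) per unit of
#'   perceived error.
#' @param w_heading,w_lateral perceived-error weights for heading deviation
#'   (rad) and lateral displacement (m).
#' @param w_rate weight (seconds) on the flow-angle proxy term, the
#'   mismatch between the path curvature the road demands and the produced
#'   yaw rate (~ the rate of change of heading deviation). Provides the
#'   anticipatory damping real drivers get from visual flow; 0 disables.
#' @param sigma_range correction rate-parameter sampling interval, seconds.
#' @param refractory minimum interval between successive correction
#'   decisions, seconds (movements may still overlap, since correction
#'   durations exceed it).
#' @param preview forward-model prediction horizon, seconds; `NULL` means
#'   `tau_d + 0.24` (the injected latency plus a typical onset-to-mode
#'   time), emulating the driver's internal compensation of their own
#'   response delay.
#' @param road_preview look-ahead time (seconds) at which the driver reads
#'   the upcoming road curvature, consistent with the 0.4-2.5 s gaze time
#'   headway.
#' @param noise_sd additive white steering-rate noise, rad/s.
#' @param seed integer RNG seed.
#' @return an `sf_driver` list.
#' @export
driver_params <- function(error_threshold = 0.02, evidence_gain = 1,
                          leak = 0.5, latency = latency_components(),
                          amplitude_gain = 2, w_heading = 1,
                          w_lateral = 0.05, w_rate = 0.4,
                          sigma_range = c(0.0707, 0.1732),
                          refractory = 0.3, preview = NULL,
                          road_preview = 1,
                          noise_sd = 0.02, seed = 1) {
  stopifnot(error_threshold > 0, evidence_gain > 0, leak >= 0,
            inherits(latency, "sf_latency"), length(sigma_range) == 2,
            sigma_range[1] > 0, sigma_range[2] < 1,
            sigma_range[2] >= sigma_range[1], noise_sd >= 0)
  structure(list(error_threshold = error_threshold,
                 evidence_gain = evidence_gain, leak = leak,
                 latency = latency, amplitude_gain = amplitude_gain,
                 w_heading = w_heading, w_lateral = w_lateral,
                 w_rate = w_rate, refractory = refractory,
                 preview = if (is.null(preview)) latency$tau_d + 0.24 else preview,
                 road_preview = road_preview,
                 sigma_range = as.numeric(sigma_range), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sf_driver")
}

#' Simulate one closed-loop drive
#'
#' Kinematic single-track vehicle (wheelbase / steering-ratio stand-in for
#' the physical vehicle) driven around the track by the intermittent
#' controller of [driver_params()]. The recorded steering rate is exactly
#' the superposition of all scheduled ballistic corrections plus the
#' injected white noise; the ground truth records every correction, its
#' trigger time and error, and the injected latency. Deterministic given
#' `driver$seed`.
#'
#' @param track an `sf_track`.
#' @param driver an `sf_driver`.
#' @param speed vehicle speed, m/s.
#' @param dt sample interval, seconds (90 Hz default).
#' @param wheelbase vehicle wheelbase, meters.
#' @param steer_ratio steering-wheel to road-wheel angle ratio.
#' @param wheel_visible condition flag carried into the trial record.
#' @param classify logical; classify the outcome (success/failure).
#' @return list with `rec` (trial record: `states` data frame,
#'   `steering_rate` signal, `outcome`, `wheel_visible`, `truncated`) and
#'   `truth` (ground truth: `corrections` set, per-correction `t_trigger`
#'   and `error`, injected `tau_d`, `noise_sd`, `tilt_bias`).
#' @export
simulate_drive <- function(track, driver = driver_params(), speed = 13,
                           dt = 1 / 90, wheelbase = 2.5, steer_ratio = 13,
                           wheel_visible = TRUE, classify = TRUE) {
  stopifnot(inherits(track, "sf_track"), inherits(driver, "sf_driver"),
            speed > 0, dt > 0)
  sec <- track$sections
  secm <- cbind(sec$s0, sec$length, sec$curvature, sec$x0, sec$y0,
                sec$heading0)
  max_steps <- as.integer(ceiling(track$total_length / speed / dt * 1.5)) + 10L

  set.seed(driver$seed)
  noise <- rnorm(max_steps, 0, driver$noise_sd)
  sigma_draws <- runif(2048, driver$sigma_range[1], driver$sigma_range[2])

  start <- track_point(track, 0, track$lane_center_offset)
  sim <- simulate_loop_cpp(secm, track$lane_center_offset,
                           track$total_length, speed, dt, wheelbase,
                           steer_ratio, driver$w_heading, driver$w_lateral,
                           driver$w_rate, driver$evidence_gain, driver$leak,
                           driver$error_threshold, driver$amplitude_gain,
                           driver$latency$tau_d, driver$refractory,
                           driver$preview, driver$road_preview,
                           sigma_draws, noise,
                           start$x, start$y, start$heading, max_steps)
  st <- sim$states
  states <- data.frame(t = st[, 1], x = st[, 2], y = st[, 3],
                       heading = st[, 4], speed = speed, vx = speed, vy = 0,
                       delta = st[, 5], rate = st[, 6], theta_h = st[, 7],
                       y_l = st[, 8], yaw_rate = st[, 9], error = st[, 10],
                       station = st[, 11])
  rec <- list(states = states,
              steering_rate = new_signal(states$rate, dt = dt, t0 = 0),
              wheel_visible = wheel_visible,
              truncated = isTRUE(sim$truncated), outcome = NA_character_)
  if (isTRUE(sim$truncated)) {
    rec$outcome <- "failure"
  } else if (classify) {
    rec$outcome <- classify_trial(rec, track)
  }
  truth <- list(corrections = correction_set(sim$a, sim$mu, sim$sigma),
                table = data.frame(a = sim$a, mu = sim$mu, sigma = sim$sigma,
                                   t_trigger = sim$t_trigger,
                                   error = sim$error),
                t_trigger = sim$t_trigger, error = sim$error,
                tau_d = driver$latency$tau_d, noise_sd = driver$noise_sd,
                noise = noise[seq_len(sim$n)], tilt_bias = 0)
  list(rec = rec, truth = truth)
}
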