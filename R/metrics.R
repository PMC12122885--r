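#' Heading deviation between road tangent and vehicle
#'
#' `theta_h = wrap(theta_road - theta_veh)` in `(-pi, pi]`. Positive values
#' mean the vehicle points to the right of the road tangent and must steer
#' left to realign.
#'
#' @param theta_road road tangent heading, radians.
#' @param theta_veh vehicle heading, radians.
#' @return heading deviation in radians, wrapped to `(-pi, pi]`.
#' @export
heading_deviation <- function(theta_road, theta_veh) {
  wrap_angle(theta_road - theta_veh)
}

#' Lateral displacement from the designated lane midline
#'
#' `y_l = y_lane - y_veh`, both measured in the road-normal frame at the
#' vehicle's arc-length station (left-positive).
#'
#' @param y_lane lateral position of the lane midline, meters.
#' @param y_veh lateral position of the vehicle, meters.
#' @return lateral displacement in meters.
#' @export
lateral_displacement <- function(y_lane, y_veh) y_lane - y_veh

#' Lateral velocity from speed and heading deviation
#'
#' Exact form `speed * sin(theta_h)` together with the small-angle
#' approximation `speed * theta_h`.
#'
#' @param speed vehicle speed, meters/second.
#' @param theta_h heading deviation, radians.
#' @return data frame with columns `exact` and `small_angle` (m/s).
#' @export
lateral_velocity_approx <- function(speed, theta_h) {
  data.frame(exact = speed * sin(theta_h), small_angle = speed * theta_h)
}

#' Lateral acceleration on a circular path
#'
#' `a = speed^2 / radius`, also reported in g-units (g = 9.81 m/s^2).
#' At 13 m/s on a 30 m radius this is ~5.63 m/s^2 (~0.57 g).
#'
#' @param speed vehicle speed, m/s.
#' @param radius path radius, m, `> 0`.
#' @param g gravitational constant, m/s^2.
#' @return list with `ms2` and `g_units`.
#' @export
lateral_acceleration <- function(speed, radius, g = 9.81) {
  if (any(radius <= 0)) stop("radius must be > 0")
  a <- speed^2 / radius
  list(ms2 = a, g_units = a / g)
}

#' Classify a trial as success or failure
#'
#' A trial fails if the vehicle ever fully exits the designated lane
#' (`|y_l| > lane_width/2 + vehicle_half_width`) or loses control
#' (`|v_y| / v_x > slip_ratio_limit` with `v_x > 0`); otherwise it is a
#' success.
#'
#' @param rec a trial record: list with a `states` data frame (`t`, `x`,
#'   `y`, `heading`, `speed`, `vx`, `vy`, `delta`).
#' @param track an `sf_track`.
#' @param slip_ratio_limit loss-of-control threshold on `|v_y|/v_x`.
#' @param vehicle_half_width vehicle half width, meters.
#' @return `"success"` or `"failure"`.
#' @export
classify_trial <- function(rec, track, slip_ratio_limit = 1,
                           vehicle_half_width = 0.75) {
  st <- rec$states
  stopifnot(is.data.frame(st), nrow(st) >= 1)
  pr <- track_project(track, st$x, st$y)
  y_l <- lateral_displacement(track$lane_center_offset, pr$lateral)
  exited <- any(abs(y_l) > track$lane_width / 2 + vehicle_half_width)
  slipped <- any(st$vx > 0 & abs(st$vy) / st$vx > slip_ratio_limit)
  if (exited || slipped) "failure" else "success"
}

#' Extract region-of-interest sample spans
#'
#' Returns half-open index spans `[start, end)` of samples whose arc-length
#' station lies inside an roi-flagged section, excluding a margin at each
#' end of the section (curve entry/exit transients).
#'
#' @param rec a trial record with a `states` data frame.
#' @param track an `sf_track`.
#' @param margin fraction of each roi section's arc length excluded at both
#'   ends.
#' @return data frame with columns `start`, `end` (1-based, half-open) and
#'   `label`.
#' @export
roi_extract <- function(rec, track, margin = 0.15) {
  st <- rec$states
  pr <- track_project(track, st$x, st$y)
  sec <- track$sections
  in_roi <- rep(FALSE, nrow(st))
  lab <- rep(NA_character_, nrow(st))
  for (i in which(sec$roi)) {
    lo <- sec$s0[i] + margin * sec$length[i]
    hi <- sec$s0[i] + (1 - margin) * sec$length[i]
    hit <- pr$section == i & pr$station >= lo & pr$station <= hi
    in_roi[hit] <- TRUE
    lab[hit] <- sec$label[i]
  }
  if (!any(in_roi)) {
    return(data.frame(start = integer(), end = integer(),
                      label = character(), stringsAsFactors = FALSE))
  }
  idx <- which(in_roi)
  grp <- cumsum(c(1L, as.integer(diff(idx) > 1L)))
  spans <- lapply(split(idx, grp), function(ix) {
    data.frame(start = min(ix), end = max(ix) + 1L, label = lab[min(ix)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, spans)
  rownames(out) <- NULL
  out
}

#' Trial outcome summary table
#'
#' Counts successes and failures split by steering-wheel visibility and
#' reports the failure occurrence as a percentage (1 decimal).
#'
#' @param records list of trial records, each with `outcome`
#'   (`"success"`/`"failure"`) and `wheel_visible` (logical); or a data
#'   frame with those columns.
#' @return data frame with rows `visible`, `not_visible`, `total`.
#' @export
summarize_trials <- function(records) {
  df <- if (is.data.frame(records)) records else {
    data.frame(outcome = vapply(records, function(r) r$outcome, ""),
               wheel_visible = vapply(records, function(r) isTRUE(r$wheel_visible), TRUE))
  }
  row_for <- function(sel, name) {
    n_s <- sum(df$outcome[sel] == "success")
    n_f <- sum(df$outcome[sel] == "failure")
    n <- n_s + n_f
    data.frame(group = name, success = n_s, failure = n_f, total = n,
               failure_pct = if (n > 0) round(100 * n_f / n, 1) else 0.0,
               stringsAsFactors = FALSE)
  }
  out <- rbind(row_for(df$wheel_visible, "visible"),
               row_for(!df$wheel_visible, "not_visible"),
               row_for(rep(TRUE, nrow(df)), "total"))
  rownames(out) <- NULL
  out
}

#' Correction-count summary table
#'
#' Row/column totals and per-trial averages for a participants x trials
#' matrix of identified correction counts. The first `n_visible` trial
#' columns are the visible-steering-wheel condition.
#'
#' @param per_trial_counts numeric matrix (participants x trials) of
#'   correction counts; may have zero rows.
#' @param n_visible number of leading trial columns in the visible-wheel
#'   condition.
#' @return list with `total`, `participant_totals`, `per_trial_total`,
#'   `per_trial_avg`, `overall_avg`, `visible_avg`, `nonvisible_avg`.
#' @export
summarize_corrections <- function(per_trial_counts, n_visible = 5) {
  m <- as.matrix(per_trial_counts)
  if (length(m) == 0 || nrow(m) == 0) {
    return(list(total = 0, participant_totals = numeric(),
                per_trial_total = numeric(), per_trial_avg = numeric(),
                overall_avg = 0, visible_avg = 0, nonvisible_avg = 0))
  }
  n_trials <- nrow(m) * ncol(m)
  vis <- seq_len(min(n_visible, ncol(m)))
  nonvis <- setdiff(seq_len(ncol(m)), vis)
  list(total = sum(m),
       participant_totals = rowSums(m),
       per_trial_total = colSums(m),
       per_trial_avg = colMeans(m),
       overall_avg = sum(m) / n_trials,
       visible_avg = if (length(vis)) sum(m[, vis]) / (nrow(m) * length(vis)) else 0,
       nonvisible_avg = if (length(nonvis)) sum(m[, nonvis]) / (nrow(m) * length(nonvis)) else 0)
}

#' Log-normal fit of absolute correction angles
#'
#' Maximum-likelihood fit of a log-normal to absolute travel distances
#' `|delta|`: `mu = mean(log d)`, `sigma2 = mean((log d - mu)^2)` (MLE,
#' 1/n variance).
#'
#' @param deltas positive absolute correction travel distances, radians.
#' @return list with `mu` and `sigma2`.
#' @export
fit_correction_angle_distribution <- function(deltas) {
  deltas <- as.numeric(deltas)
  if (length(deltas) == 0) stop("no deltas")
  if (any(!is.finite(deltas)) || any(deltas <= 0)) {
    stop("all deltas must be finite and > 0")
  }
  l <- log(deltas)
  mu <- mean(l)
  list(mu = mu, sigma2 = mean((l - mu)^2))
}
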