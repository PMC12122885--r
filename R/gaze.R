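#' Smooth-pursuit gaze model over a simulated drive
#'
#' Emulates lane-directed gaze during driving: fixation targets are drawn
#' on the designated lane at a sampled headway (biased laterally toward the
#' inner curve edge), the gaze tracks each fixed ground point exactly while
#' it dwells (pursuit gain 1.0), and saccade gaps between fixations emit
#' invalid samples. Confidence is high within fixations with an occasional
#' sub-cutoff draw, mimicking eye-tracker dropouts.
#'
#' @param rec a trial record from [simulate_drive()].
#' @param track an `sf_track`.
#' @param camera an [camera_model()] used to project gaze to screen
#'   coordinates.
#' @param headway_range fixation headway interval, meters (within the
#'   observed 4-25 m).
#' @param dwell_range fixation dwell duration interval, seconds.
#' @param inner_bias mean lateral shift of fixation targets toward the
#'   inner curve edge, meters (0 on straights).
#' @param lateral_sd lateral scatter of fixation targets, meters.
#' @param saccade_duration gap between fixations, seconds (invalid
#'   samples).
#' @param low_conf_rate probability that a within-fixation sample draws a
#'   sub-0.6 confidence.
#' @param seed integer RNG seed.
#' @return list with `samples` (data frame `t`, `x`, `y` normalized,
#'   `confidence`, `valid`), `ground` (per-sample fixated world point,
#'   `NA` during saccades), and `fixations` (one row per fixation:
#'   `t_on`, `t_off`, `gx`, `gy`, `headway`).
#' @export
gaze_model <- function(rec, track, camera = camera_model(),
                       headway_range = c(4, 25), dwell_range = c(0.3, 1),
                       inner_bias = 0.5, lateral_sd = 0.6,
                       saccade_duration = 0.06, low_conf_rate = 0.05,
                       seed = 1) {
  stopifnot(inherits(track, "sf_track"), inherits(camera, "sf_camera"),
            headway_range[1] >= 0, headway_range[2] >= headway_range[1])
  st <- rec$states
  n <- nrow(st)
  set.seed(seed)

  tvec <- st$t
  x_n <- rep(NA_real_, n); y_n <- rep(NA_real_, n)
  conf <- rep(NA_real_, n); valid <- rep(FALSE, n)
  gx <- rep(NA_real_, n); gy <- rep(NA_real_, n)
  fix_rows <- list()

  half_usable <- track$lane_width / 2 - 0.3
  i <- 1L
  while (i <= n) {
    # pick a fixation target from the vehicle's current station
    d_h <- runif(1, headway_range[1], headway_range[2])
    s_target <- st$station[i] + d_h
    p0 <- track_point(track, s_target, 0)
    bias <- if (p0$curvature > 0) inner_bias else if (p0$curvature < 0) -inner_bias else 0
    lat <- track$lane_center_offset + rnorm(1, bias, lateral_sd)
    lat <- min(max(lat, track$lane_center_offset - half_usable),
               track$lane_center_offset + half_usable)
    pt <- track_point(track, s_target, lat)

    dwell <- runif(1, dwell_range[1], dwell_range[2])
    i_end <- min(n, i + max(1L, round(dwell / (tvec[2] - tvec[1]))) - 1L)
    for (j in i:i_end) {
      eye <- c(st$x[j], st$y[j], camera$height)
      b <- camera_basis(camera, st$heading[j])
      pr <- project_points(matrix(c(pt$x, pt$y, 0), 1), eye, b, camera)
      if (pr$in_front[1] && is.finite(pr$u[1])) {
        x_n[j] <- pr$u[1] / camera$width
        y_n[j] <- pr$w[1] / camera$height_px
        valid[j] <- x_n[j] >= 0 && x_n[j] <= 1 && y_n[j] >= 0 && y_n[j] <= 1
      }
      conf[j] <- if (runif(1) < low_conf_rate) runif(1, 0.2, 0.6) else runif(1, 0.75, 1)
      gx[j] <- pt$x; gy[j] <- pt$y
    }
    fix_rows[[length(fix_rows) + 1L]] <-
      data.frame(t_on = tvec[i], t_off = tvec[i_end], gx = pt$x, gy = pt$y,
                 headway = d_h)
    # saccade gap: invalid samples
    i <- i_end + 1L
    n_sac <- max(1L, round(saccade_duration / (tvec[2] - tvec[1])))
    if (i <= n) {
      j_end <- min(n, i + n_sac - 1L)
      conf[i:j_end] <- runif(j_end - i + 1L, 0, 0.5)
      valid[i:j_end] <- FALSE
      i <- j_end + 1L
    }
  }
  x_n[is.na(x_n)] <- 0.5; y_n[is.na(y_n)] <- 0.5
  list(samples = data.frame(t = tvec, x = x_n, y = y_n, confidence = conf,
                            valid = valid),
       ground = data.frame(t = tvec, gx = gx, gy = gy),
       fixations = do.call(rbind, fix_rows))
}
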