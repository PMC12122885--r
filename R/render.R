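#' Pinhole camera model for the analytic flow renderer
#'
#' The camera sits at the driver's eye height above the ground plane,
#' pointing along the vehicle heading with a fixed downward pitch (and an
#' optional roll emulating head tilt). Image convention: origin top-left,
#' x rightward, y downward.
#'
#' @param height eye height above the ground, meters (~1.1 m seated under
#'   an HMD).
#' @param focal_length focal length, pixels.
#' @param image_size `c(width, height)` in pixels. The default 360 x 400
#'   raster is a quarter-linear-scale stand-in for a 1440 x 1600 HMD eye.
#' @param pitch downward camera pitch, radians (positive looks down).
#' @param roll camera roll about the optical axis, radians.
#' @return an `sf_camera` object.
#' @export
camera_model <- function(height = 1.1, focal_length = 160,
                         image_size = c(360, 400), pitch = 0.15, roll = 0) {
  stopifnot(height > 0, focal_length > 0, length(image_size) == 2,
            all(image_size >= 8), abs(pitch) < pi / 2)
  structure(list(height = height, focal_length = focal_length,
                 width = as.integer(image_size[1]),
                 height_px = as.integer(image_size[2]),
                 cx = (image_size[1] + 1) / 2, cy = (image_size[2] + 1) / 2,
                 pitch = pitch, roll = roll),
            class = "sf_camera")
}

# world-frame camera basis (forward, right, down) for a pose
camera_basis <- function(camera, heading) {
  p <- camera$pitch; ro <- camera$roll
  ch <- cos(heading); sh <- sin(heading)
  f_h <- c(cos(p), 0, -sin(p))        # heading-aligned frame: x fwd, y left, z up
  r_h <- c(0, -1, 0)
  d_h <- c(-sin(p), 0, -cos(p))       # f x r
  r_roll <- cos(ro) * r_h + sin(ro) * d_h
  d_roll <- -sin(ro) * r_h + cos(ro) * d_h
  rot <- function(v) c(ch * v[1] - sh * v[2], sh * v[1] + ch * v[2], v[3])
  list(f = rot(f_h), r = rot(r_roll), d = rot(d_roll))
}

# project world points (matrix nx3) to pixels for an eye/basis; returns
# data.frame(u, w, in_front)
project_points <- function(P, eye, basis, camera) {
  qx <- P[, 1] - eye[1]; qy <- P[, 2] - eye[2]; qz <- P[, 3] - eye[3]
  qf <- qx * basis$f[1] + qy * basis$f[2] + qz * basis$f[3]
  qr <- qx * basis$r[1] + qy * basis$r[2] + qz * basis$r[3]
  qd <- qx * basis$d[1] + qy * basis$d[2] + qz * basis$d[3]
  ok <- qf > 1e-9
  data.frame(u = ifelse(ok, camera$cx + camera$focal_length * qr / qf, NA_real_),
             w = ifelse(ok, camera$cy + camera$focal_length * qd / qf, NA_real_),
             in_front = ok)
}

#' Analytic dense ground-plane optic flow
#'
#' For every pixel whose viewing ray hits the ground plane, the world point
#' is back-projected and its instantaneous image velocity under the
#' vehicle's rigid motion (translation + yaw) is evaluated in closed form
#' (the exact time derivative of the pinhole projection, in
#' pixels/second — frame-rate independent). Above-horizon (and beyond
#' `max_range`) pixels carry zero flow and are mask-excluded. The lane
#' mask is the exact projection of the designated-lane region; the gaze
#' pixel is the projection of the fixated ground point.
#'
#' @param state one row of a vehicle-state data frame (`x`, `y`, `heading`,
#'   `vx`, `vy`, optionally `yaw_rate`).
#' @param camera an [camera_model()].
#' @param track an `sf_track` (used for the lane mask).
#' @param gaze_ground fixated ground point `c(x, y)` or `c(x, y, 0)` in
#'   world meters, or `NULL`.
#' @param dt frame interval, seconds (metadata; also used to derive the
#'   motion from `next_state` when given).
#' @param next_state optional next-frame state row; when given, the
#'   world-frame velocity and yaw rate are taken as the finite pose
#'   difference over `dt` instead of the instantaneous state fields.
#' @param max_range ground points beyond this distance (m) are treated as
#'   sky (zero flow, mask-excluded).
#' @return list with `flow` (`sf_flow`), `mask` (logical matrix),
#'   `gaze_px` (`c(x, y)` or `NULL`), `gaze_valid`, and `ground_valid`
#'   (logical matrix of pixels that hit the ground).
#' @export
render_flow <- function(state, camera, track, gaze_ground = NULL, dt = 1 / 90,
                        next_state = NULL, max_range = 500) {
  stopifnot(inherits(camera, "sf_camera"), dt > 0)
  eye1 <- c(state$x, state$y, camera$height)
  b1 <- camera_basis(camera, state$heading)
  if (is.null(next_state)) {
    yr <- if (!is.null(state$yaw_rate)) state$yaw_rate else 0
    ch <- cos(state$heading); sh <- sin(state$heading)
    wx <- state$vx * ch - state$vy * sh
    wy <- state$vx * sh + state$vy * ch
  } else {
    wx <- (next_state$x - state$x) / dt
    wy <- (next_state$y - state$y) / dt
    yr <- (next_state$heading - state$heading) / dt
  }

  W <- camera$width; H <- camera$height_px; fl <- camera$focal_length
  u <- matrix(rep(seq_len(W), each = H), nrow = H)
  w <- matrix(rep(seq_len(H), times = W), nrow = H)
  a <- (u - camera$cx) / fl
  b <- (w - camera$cy) / fl
  rx <- b1$f[1] + a * b1$r[1] + b * b1$d[1]
  ry <- b1$f[2] + a * b1$r[2] + b * b1$d[2]
  rz <- b1$f[3] + a * b1$r[3] + b * b1$d[3]
  hit <- rz < -1e-6
  sdist <- ifelse(hit, camera$height / pmax(-rz, 1e-12), NA_real_)
  Px <- eye1[1] + sdist * rx
  Py <- eye1[2] + sdist * ry
  range2 <- (Px - eye1[1])^2 + (Py - eye1[2])^2
  hit <- hit & is.finite(range2) & range2 <= max_range^2

  # closed-form image velocity: q = P - e, qdot = -(wx, wy, 0); the basis
  # rotates with the yaw rate, adot = omega x a with omega = yr * z_hat
  vy_m <- matrix(0, H, W); vz_m <- matrix(0, H, W)
  idx <- which(hit)
  if (length(idx)) {
    qx <- Px[idx] - eye1[1]; qy <- Py[idx] - eye1[2]; qz <- -camera$height
    dot3 <- function(ax, ay, az, v) ax * v[1] + ay * v[2] + az * v[3]
    cross_w <- function(v) c(-yr * v[2], yr * v[1], 0)  # omega x v
    qf <- dot3(qx, qy, qz, b1$f); qr <- dot3(qx, qy, qz, b1$r)
    qd <- dot3(qx, qy, qz, b1$d)
    qdot_f <- -(wx * b1$f[1] + wy * b1$f[2]) + dot3(qx, qy, qz, cross_w(b1$f))
    qdot_r <- -(wx * b1$r[1] + wy * b1$r[2]) + dot3(qx, qy, qz, cross_w(b1$r))
    qdot_d <- -(wx * b1$d[1] + wy * b1$d[2]) + dot3(qx, qy, qz, cross_w(b1$d))
    ok <- qf > 1e-9
    vy_m[idx[ok]] <- (fl * (qdot_r * qf - qr * qdot_f) / qf^2)[ok]
    vz_m[idx[ok]] <- (fl * (qdot_d * qf - qd * qdot_f) / qf^2)[ok]
    hit[idx[!ok]] <- FALSE
  }

  mask <- matrix(FALSE, H, W)
  idx <- which(hit)
  if (length(idx)) {
    prj <- track_project(track, Px[idx], Py[idx])
    in_lane <- abs(prj$lateral - track$lane_center_offset) <= track$lane_width / 2
    mask[idx] <- in_lane
  }

  gaze_px <- NULL; gaze_valid <- FALSE
  if (!is.null(gaze_ground)) {
    g3 <- c(gaze_ground[1], gaze_ground[2],
            if (length(gaze_ground) >= 3) gaze_ground[3] else 0)
    gp <- project_points(matrix(g3, 1), eye1, b1, camera)
    if (gp$in_front[1] && is.finite(gp$u[1]) &&
        gp$u[1] >= 1 && gp$u[1] <= W && gp$w[1] >= 1 && gp$w[1] <= H) {
      gaze_px <- c(gp$u[1], gp$w[1]); gaze_valid <- TRUE
    }
  }

  flow <- flow_field(vy_m, vz_m, fl, c(camera$cx, camera$cy), dt)
  list(flow = flow, mask = mask, gaze_px = gaze_px, gaze_valid = gaze_valid,
       ground_valid = hit)
}

#' Inject a constant camera-tilt bias into a rendered frame
#'
#' Emulates a tilted head / misaligned headset by rotating the whole image
#' about the principal point: the flow raster, lane mask and ground-valid
#' mask are resampled from the nearest inverse-rotated source pixel, the
#' sampled flow vectors are rotated by `tilt`, and the gaze pixel is
#' rotated exactly. The accumulated tilt is tracked in `attr(, "tilt")`
#' (exact under composition); raster content composes up to
#' nearest-neighbour rounding.
#'
#' @param frame a frame list as returned by [render_flow()].
#' @param tilt tilt angle, radians, `|tilt| < pi/4`.
#' @return the tilted frame.
#' @export
inject_camera_tilt <- function(frame, tilt) {
  stopifnot(abs(tilt) < pi / 4)
  ct <- cos(tilt); st <- sin(tilt)
  v <- frame$flow
  cx <- v$principal_point[1]; cy <- v$principal_point[2]
  H <- v$height; W <- v$width
  u <- matrix(rep(seq_len(W), each = H), nrow = H)
  w <- matrix(rep(seq_len(H), times = W), nrow = H)
  # image rotated by `tilt`: destination pixel takes the inverse-rotated
  # source pixel (rotation by -tilt in image coordinates)
  du <- u - cx; dw <- w - cy
  su <- round(cx + ct * du + st * dw)
  sw <- round(cy - st * du + ct * dw)
  ok <- su >= 1 & su <= W & sw >= 1 & sw <= H
  src <- cbind(sw[ok], su[ok])
  take <- function(m, fill) {
    m2 <- matrix(fill, H, W)
    m2[ok] <- m[src]
    m2
  }
  vy_s <- take(v$vy, 0); vz_s <- take(v$vz, 0)
  frame$flow <- flow_field(ct * vy_s - st * vz_s, st * vy_s + ct * vz_s,
                           v$focal_length, v$principal_point, v$dt)
  if (!is.null(frame$mask)) frame$mask <- take(frame$mask, FALSE)
  if (!is.null(frame$ground_valid)) {
    frame$ground_valid <- take(frame$ground_valid, FALSE)
  }
  if (!is.null(frame$gaze_px)) {
    dg <- frame$gaze_px - c(cx, cy)
    frame$gaze_px <- c(cx + ct * dg[1] - st * dg[2],
                       cy + st * dg[1] + ct * dg[2])
  }
  attr(frame, "tilt") <- (if (is.null(attr(frame, "tilt"))) 0 else attr(frame, "tilt")) + tilt
  frame
}
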