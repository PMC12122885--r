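#' Dense optic flow field container
#'
#' Per-pixel 2-D image-plane motion on a raster, with pinhole camera
#' metadata. Image convention: origin top-left, `vy` is the rightward
#' (column) component and `vz` the downward (row) component, both in
#' pixels/second; "straight down" flow therefore has direction `+pi/2`.
#'
#' @param vy,vz numeric matrices (height x width), pixels/second.
#' @param focal_length focal length in pixels.
#' @param principal_point `c(x, y)` pixel coordinates of the principal
#'   point (1-based, x = column).
#' @param dt frame interval the flow was derived from, seconds (metadata).
#' @return an `sf_flow` object.
#' @export
flow_field <- function(vy, vz, focal_length, principal_point = NULL, dt = NA_real_) {
  vy <- as.matrix(vy); vz <- as.matrix(vz)
  stopifnot(all(dim(vy) == dim(vz)), all(is.finite(vy)), all(is.finite(vz)),
            focal_length > 0)
  if (is.null(principal_point)) {
    principal_point <- c((ncol(vy) + 1) / 2, (nrow(vy) + 1) / 2)
  }
  structure(list(vy = vy, vz = vz, width = ncol(vy), height = nrow(vy),
                 focal_length = focal_length,
                 principal_point = as.numeric(principal_point), dt = dt),
            class = "sf_flow")
}

#' @export
print.sf_flow <- function(x, ...) {
  cat(sprintf("<sf_flow> %dx%d px, f=%.4g px\n", x$width, x$height,
              x$focal_length))
  invisible(x)
}

bilinear_at <- function(m, px) {
  xx <- px[1]; yy <- px[2]
  x0 <- floor(xx); y0 <- floor(yy)
  x0 <- min(max(x0, 1), ncol(m) - 1L); y0 <- min(max(y0, 1), nrow(m) - 1L)
  fx <- xx - x0; fy <- yy - y0
  fx <- min(max(fx, 0), 1); fy <- min(max(fy, 0), 1)
  (1 - fx) * (1 - fy) * m[y0, x0] + fx * (1 - fy) * m[y0, x0 + 1] +
    (1 - fx) * fy * m[y0 + 1, x0] + fx * fy * m[y0 + 1, x0 + 1]
}

#' Retinal optic flow from a flow field and a gaze point
#'
#' Subtracts the (bilinearly interpolated) flow at the gaze pixel from the
#' whole field, emulating the retinal image stabilization of a gaze
#' fixation / smooth pursuit with gain 1: the retinal flow at the gaze
#' pixel is exactly the zero vector.
#'
#' @param v an `sf_flow`.
#' @param gaze_px gaze pixel `c(x, y)` (1-based, may be fractional); must
#'   lie inside the raster.
#' @return an `sf_flow` of the retinal flow; the nearest pixel to the gaze
#'   point is set exactly to zero.
#' @export
retinal_flow_field <- function(v, gaze_px) {
  stopifnot(inherits(v, "sf_flow"), length(gaze_px) == 2)
  if (gaze_px[1] < 1 || gaze_px[1] > v$width ||
      gaze_px[2] < 1 || gaze_px[2] > v$height) {
    stop("gaze point outside raster")
  }
  gy <- bilinear_at(v$vy, gaze_px)
  gz <- bilinear_at(v$vz, gaze_px)
  out <- flow_field(v$vy - gy, v$vz - gz, v$focal_length, v$principal_point,
                    v$dt)
  # exact null at the fovea: the nearest raster pixel is zeroed even when
  # the sub-pixel gaze interpolation leaves a residual there
  ix <- round(gaze_px[1]); iy <- round(gaze_px[2])
  out$vy[iy, ix] <- 0; out$vz[iy, ix] <- 0
  attr(out, "gaze_px") <- as.numeric(gaze_px)
  out
}

#' Angular direction of flow vectors
#'
#' Full-quadrant angle `atan2(vz, vy)` in `(-pi, pi]`; zero vectors have no
#' direction and return `NA`.
#'
#' @param vy,vz vector components (rightward, downward), same shape.
#' @return angles in radians, `NA` for zero vectors.
#' @export
flow_direction <- function(vy, vz) {
  ang <- atan2(vz, vy)
  ang[vy == 0 & vz == 0] <- NA_real_
  ang
}

#' Lane-masked circular mean retinal flow angle
#'
#' Spatial circular mean of the flow directions over the masked (lane)
#' pixels, all pixels equally weighted; zero-magnitude vectors are excluded
#' since their direction is undefined.
#'
#' @param v_r retinal `sf_flow`.
#' @param mask logical matrix of lane membership, same dims as the field.
#' @return list with `angle` (radians, `NA` when invalid), `valid`
#'   (logical) and `n` (pixels used).
#' @export
rof_angle <- function(v_r, mask) {
  stopifnot(inherits(v_r, "sf_flow"), is.matrix(mask) | is.logical(mask))
  mask <- matrix(as.logical(mask), nrow = v_r$height)
  stopifnot(all(dim(mask) == c(v_r$height, v_r$width)))
  ang <- flow_direction(v_r$vy[mask], v_r$vz[mask])
  ang <- ang[!is.na(ang)]
  if (length(ang) == 0) {
    return(list(angle = NA_real_, valid = FALSE, n = 0L))
  }
  a <- tryCatch(circular_mean_angle(ang), error = function(e) NA_real_)
  list(angle = a, valid = is.finite(a), n = length(ang))
}

#' Filter gaze samples by confidence and screen position
#'
#' Keeps samples with confidence of at least 0.6, normalized screen
#' position strictly inside the central 60 % of the screen (outside the
#' extreme 20 % border perimeter), and not blink-flagged. Idempotent.
#'
#' @param samples data frame with columns `t`, `x`, `y` (normalized
#'   `[0, 1]`), `confidence` and `valid` (FALSE marks blinks/dropouts).
#' @param min_confidence confidence cutoff.
#' @param border excluded border fraction on each side.
#' @return the accepted subset of `samples`.
#' @export
filter_gaze <- function(samples, min_confidence = 0.6, border = 0.2) {
  stopifnot(all(c("t", "x", "y", "confidence") %in% names(samples)))
  ok_valid <- if ("valid" %in% names(samples)) samples$valid else TRUE
  keep <- samples$confidence >= min_confidence &
    samples$x > border & samples$x < 1 - border &
    samples$y > border & samples$y < 1 - border &
    ok_valid
  samples[keep & !is.na(keep), , drop = FALSE]
}

#' Retinal flow angle series
#'
#' @param t sample times, seconds.
#' @param angle angles, radians (wrapped to `(-pi, pi]`).
#' @param valid logical validity flags.
#' @return an `sf_rof_series` data frame.
#' @export
rof_series <- function(t, angle, valid = is.finite(angle)) {
  stopifnot(length(t) == length(angle), length(valid) == length(t))
  structure(data.frame(t = t, angle = ifelse(valid, wrap_angle(angle), angle),
                       valid = valid),
            class = c("sf_rof_series", "data.frame"))
}

#' Remove the constant camera-tilt bias from a flow-angle series
#'
#' Subtracts the circular median of the valid samples taken during straight
#' track sections from every sample, re-centering the series so the
#' straight-section median is ~0. The subtracted bias is returned as an
#' attribute.
#'
#' @param series an `sf_rof_series`.
#' @param straight_mask logical per-sample flags marking straight-section
#'   samples.
#' @param min_samples minimum number of valid straight samples required.
#' @return the recentered `sf_rof_series` with attribute `bias` (radians).
#' @export
detilt <- function(series, straight_mask, min_samples = 10) {
  stopifnot(inherits(series, "sf_rof_series"),
            length(straight_mask) == nrow(series))
  sel <- straight_mask & series$valid
  if (sum(sel) < min_samples) {
    stop(sprintf("need >= %d valid straight-section samples, have %d",
                 min_samples, sum(sel)))
  }
  bias <- circular_median_angle(series$angle[sel])
  out <- rof_series(series$t,
                    ifelse(series$valid, wrap_angle(series$angle - bias),
                           series$angle),
                    series$valid)
  attr(out, "bias") <- bias
  out
}

#' Distance and time headway of a gaze fixation
#'
#' Euclidean distance from the eye to the fixated ground point, and that
#' distance divided by the vehicle speed.
#'
#' @param eye_position 3-D eye position, meters.
#' @param gaze_ground_point 3-D fixated point, meters.
#' @param speed vehicle speed, m/s.
#' @return list with `d_h` (m) and `t_h` (s; `NA` when `speed <= 0`).
#' @export
gaze_headway <- function(eye_position, gaze_ground_point, speed) {
  stopifnot(length(eye_position) == 3, length(gaze_ground_point) == 3)
  d <- sqrt(sum((eye_position - gaze_ground_point)^2))
  list(d_h = d, t_h = if (speed > 0) d / speed else NA_real_)
}

#' Flow field / lane mask binary I/O
#'
#' Flow fields are stored as row-major 32-bit float binary with two planes
#' (`vy` then `vz`) and a JSON sidecar holding `width`, `height`,
#' `focal_length`, `principal_point` and `dt`. Lane masks are 8-bit rasters
#' with the same sidecar layout. An external dense-flow provider can supply
#' files in this format in place of the built-in analytic renderer.
#'
#' @param v an `sf_flow`.
#' @param path binary file path; the sidecar is written at `<path>.json`.
#' @return readers return the reconstructed object.
#' @export
write_flow_field <- function(v, path) {
  stopifnot(inherits(v, "sf_flow"))
  con <- file(path, "wb")
  on.exit(close(con))
  # row-major planes: transpose because R matrices are column-major
  writeBin(as.numeric(t(v$vy)), con, size = 4)
  writeBin(as.numeric(t(v$vz)), con, size = 4)
  jsonlite::write_json(list(width = v$width, height = v$height,
                            focal_length = v$focal_length,
                            principal_point = v$principal_point, dt = v$dt),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_flow_field
#' @export
read_flow_field <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- meta$width * meta$height
  con <- file(path, "rb")
  on.exit(close(con))
  vy <- matrix(readBin(con, "numeric", n, size = 4), nrow = meta$height,
               byrow = TRUE)
  vz <- matrix(readBin(con, "numeric", n, size = 4), nrow = meta$height,
               byrow = TRUE)
  flow_field(vy, vz, meta$focal_length, meta$principal_point,
             if (is.null(meta$dt)) NA_real_ else meta$dt)
}

#' @rdname write_flow_field
#' @param mask logical matrix.
#' @export
write_lane_mask <- function(mask, path, focal_length = 1,
                            principal_point = NULL) {
  mask <- as.matrix(mask)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(t(mask)), con, size = 1)
  jsonlite::write_json(list(width = ncol(mask), height = nrow(mask),
                            focal_length = focal_length,
                            principal_point = principal_point),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_flow_field
#' @export
read_lane_mask <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- meta$width * meta$height
  con <- file(path, "rb")
  on.exit(close(con))
  matrix(readBin(con, "integer", n, size = 1, signed = FALSE) > 0,
         nrow = meta$height, byrow = TRUE)
}
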