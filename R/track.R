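#' S-shaped test track geometry
#'
#' Builds the default experimental track: an acceleration straight, a left
#' semi-circular curve bend, a short connecting straight, a right
#' semi-circular bend and a deceleration straight. Curve bends have a 60 m
#' diameter by default. The centerline is arc-length parameterized; lateral
#' offsets are signed positive to the left of the travel direction, and the
#' designated driving lane midline sits `lane_center_offset` from the road
#' centerline.
#'
#' @param curve_diameter curve bend diameter in meters.
#' @param lane_width designated lane width in meters.
#' @param straight_lengths lengths in meters of the acceleration, middle
#'   and deceleration straights.
#' @param lane_center_offset signed offset (m, left-positive) from the road
#'   centerline to the designated lane midline. Default `-lane_width / 2`
#'   (right lane of a two-lane road).
#' @return an `sf_track` object with a `sections` data frame (`label`,
#'   `type`, `length`, `curvature`, start pose, `roi`), `lane_width`,
#'   `lane_center_offset`, `curve_radius` and `total_length`.
#' @examples
#' trk <- build_track()
#' trk$curve_radius          # 30
#' @export
build_track <- function(curve_diameter = 60, lane_width = 3.5,
                        straight_lengths = c(100, 20, 100),
                        lane_center_offset = NULL) {
  stopifnot(curve_diameter > 0, lane_width > 0, all(straight_lengths > 0),
            length(straight_lengths) == 3)
  if (is.null(lane_center_offset)) lane_center_offset <- -lane_width / 2
  r <- curve_diameter / 2
  specs <- list(
    list(label = "accel",       type = "straight", length = straight_lengths[1], curvature = 0,      roi = FALSE),
    list(label = "left_curve",  type = "arc",      length = pi * r,              curvature = 1 / r,  roi = TRUE),
    list(label = "straight",    type = "straight", length = straight_lengths[2], curvature = 0,      roi = FALSE),
    list(label = "right_curve", type = "arc",      length = pi * r,              curvature = -1 / r, roi = TRUE),
    list(label = "decel",       type = "straight", length = straight_lengths[3], curvature = 0,      roi = FALSE))
  x <- 0; y <- 0; h <- 0; s <- 0
  rows <- lapply(specs, function(sp) {
    row <- data.frame(label = sp$label, type = sp$type, length = sp$length,
                      curvature = sp$curvature, x0 = x, y0 = y, heading0 = h,
                      s0 = s, roi = sp$roi, stringsAsFactors = FALSE)
    if (sp$type == "straight") {
      x <<- x + sp$length * cos(h); y <<- y + sp$length * sin(h)
    } else {
      k <- sp$curvature
      cx <- x - sin(h) / k; cy <- y + cos(h) / k
      h1 <- h + k * sp$length
      x <<- cx + sin(h1) / k; y <<- cy - cos(h1) / k
      h <<- h1
    }
    s <<- s + sp$length
    row
  })
  structure(list(sections = do.call(rbind, rows), lane_width = lane_width,
                 lane_center_offset = lane_center_offset, curve_radius = r,
                 total_length = s),
            class = "sf_track")
}

#' @export
print.sf_track <- function(x, ...) {
  cat(sprintf("<sf_track> %d sections, total %.1f m, curve radius %.1f m, lane %.2f m\n",
              nrow(x$sections), x$total_length, x$curve_radius, x$lane_width))
  invisible(x)
}

#' Centerline pose at an arc-length station
#'
#' @param track an `sf_track`.
#' @param station arc length(s) along the centerline, meters (clamped to
#'   the track span).
#' @param lateral signed lateral offset(s), meters, left-positive.
#' @return data frame with `x`, `y`, `heading`, `curvature`, `label`.
#' @export
track_point <- function(track, station, lateral = 0) {
  stopifnot(inherits(track, "sf_track"))
  station <- pmin(pmax(station, 0), track$total_length)
  lateral <- rep_len(lateral, length(station))
  sec <- track$sections
  idx <- findInterval(station, c(sec$s0, track$total_length),
                      rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nrow(sec))
  s_loc <- station - sec$s0[idx]
  h0 <- sec$heading0[idx]; k <- sec$curvature[idx]
  x <- numeric(length(station)); y <- x; h <- x
  st <- k == 0
  h[st] <- h0[st]
  x[st] <- sec$x0[idx][st] + s_loc[st] * cos(h0[st])
  y[st] <- sec$y0[idx][st] + s_loc[st] * sin(h0[st])
  if (any(!st)) {
    a <- !st
    cx <- sec$x0[idx][a] - sin(h0[a]) / k[a]
    cy <- sec$y0[idx][a] + cos(h0[a]) / k[a]
    h[a] <- h0[a] + k[a] * s_loc[a]
    x[a] <- cx + sin(h[a]) / k[a]
    y[a] <- cy - cos(h[a]) / k[a]
  }
  # left normal is (-sin h, cos h); apply lateral offset
  data.frame(x = x - lateral * sin(h), y = y + lateral * cos(h),
             heading = h, curvature = k, label = sec$label[idx],
             stringsAsFactors = FALSE)
}

#' Project world points onto the track centerline
#'
#' Nearest-point projection; ties between sections resolve to the smaller
#' arc length. Vectorized over points.
#'
#' @param track an `sf_track`.
#' @param x,y world coordinates, meters.
#' @return data frame with `station` (m), `lateral` (m, left-positive),
#'   `heading` (road tangent, rad), `section` (index), `label`.
#' @export
track_project <- function(track, x, y) {
  stopifnot(inherits(track, "sf_track"))
  n <- length(x)
  stopifnot(length(y) == n)
  best_d <- rep(Inf, n)
  station <- numeric(n); lateral <- numeric(n); heading <- numeric(n)
  section <- integer(n)
  sec <- track$sections
  for (i in seq_len(nrow(sec))) {
    L <- sec$length[i]; h0 <- sec$heading0[i]; k <- sec$curvature[i]
    if (k == 0) {
      dx <- x - sec$x0[i]; dy <- y - sec$y0[i]
      along <- dx * cos(h0) + dy * sin(h0)
      lat <- -dx * sin(h0) + dy * cos(h0)
      s_cl <- pmin(pmax(along, 0), L)
      fx <- sec$x0[i] + s_cl * cos(h0); fy <- sec$y0[i] + s_cl * sin(h0)
      d <- sqrt((x - fx)^2 + (y - fy)^2)
      h_at <- rep(h0, n)
      lat_at <- lat
    } else {
      cx <- sec$x0[i] - sin(h0) / k; cy <- sec$y0[i] + cos(h0) / k
      phi0 <- atan2(sec$y0[i] - cy, sec$x0[i] - cx)
      phi <- atan2(y - cy, x - cx)
      dphi <- (phi - phi0) %% (2 * pi)          # CCW angle from start
      s_raw <- if (k > 0) dphi / k else (dphi - 2 * pi) / k
      s_cl <- pmin(pmax(s_raw, 0), L)
      p <- track_point(track, sec$s0[i] + s_cl, 0)
      d_int <- sqrt((x - p$x)^2 + (y - p$y)^2)
      dq <- sqrt((x - cx)^2 + (y - cy)^2)
      interior <- s_raw >= 0 & s_raw <= L
      d <- ifelse(interior, abs(sign(k) * (1 / abs(k) - dq)), d_int)
      h_at <- p$heading
      lat_at <- sign(k) * (1 / abs(k) - dq)
      # off-span points: lateral measured to the clamped endpoint frame
      if (any(!interior)) {
        dxe <- x - p$x; dye <- y - p$y
        lat_at[!interior] <- (-dxe * sin(h_at) + dye * cos(h_at))[!interior]
        d[!interior] <- d_int[!interior]
      }
    }
    better <- d < best_d - 1e-12
    best_d[better] <- d[better]
    station[better] <- sec$s0[i] + s_cl[better]
    lateral[better] <- lat_at[better]
    heading[better] <- h_at[better]
    section[better] <- i
  }
  data.frame(station = station, lateral = lateral, heading = heading,
             section = section, label = sec$label[section],
             stringsAsFactors = FALSE)
}

#' Serialize a track to / from JSON
#'
#' @param track an `sf_track`.
#' @param path file path.
#' @return `read_track` returns an `sf_track`.
#' @export
write_track <- function(track, path) {
  stopifnot(inherits(track, "sf_track"))
  jsonlite::write_json(
    list(sections = track$sections, lane_width = track$lane_width,
         lane_center_offset = track$lane_center_offset,
         curve_radius = track$curve_radius,
         total_length = track$total_length),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(sections = as.data.frame(o$sections),
                 lane_width = o$lane_width,
                 lane_center_offset = o$lane_center_offset,
                 curve_radius = o$curve_radius, total_length = o$total_length),
            class = "sf_track")
}
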