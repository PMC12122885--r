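make_flow <- function(vy, vz, fl = 100) flow_field(vy, vz, focal_length = fl)

test_that("wrap and circular mean behave on the circle", {
  expect_equal(wrap_angle(-6.2), -6.2 + 2 * pi, tolerance = 1e-12)
  expect_equal(wrap_angle(pi), pi)
  expect_equal(wrap_angle(-pi), pi)
  expect_equal(circular_mean_angle(rep(pi / 2, 3)), pi / 2)
  expect_equal(circular_mean_angle(c(3, -3)), pi)     # not the arithmetic 0
  expect_error(circular_mean_angle(c(0, pi)), "undefined")
  expect_error(circular_mean_angle(numeric()), "empty")
  # rotation equivariance
  set.seed(1)
  for (r in 1:20) {
    ang <- runif(sample(3:40, 1), -pi, pi) * 0.3 + runif(1, -pi, pi)
    rot <- runif(1, -pi, pi)
    expect_equal(wrap_angle(circular_mean_angle(ang + rot)),
                 wrap_angle(circular_mean_angle(ang) + rot),
                 tolerance = 1e-9)
  }
})

test_that("circular median minimizes summed absolute circular deviation", {
  set.seed(2)
  ang <- wrap_angle(rnorm(25, 2.9, 0.3))              # cluster near the cut
  med <- circular_median_angle(ang)
  dev <- vapply(ang, function(a) sum(abs(wrap_angle(ang - a))), 0)
  expect_equal(sum(abs(wrap_angle(ang - med))), min(dev))
})

test_that("retinal flow subtracts the gaze-point flow exactly", {
  set.seed(3)
  vy <- matrix(rnorm(1200), 30); vz <- matrix(rnorm(1200), 30)
  v <- make_flow(vy, vz)
  vr <- retinal_flow_field(v, c(17.3, 11.6))
  gp <- c(round(17.3), round(11.6))
  expect_identical(vr$vy[gp[2], gp[1]], 0)
  expect_identical(vr$vz[gp[2], gp[1]], 0)
  # spatially uniform field -> identically zero retinal field
  vu <- make_flow(matrix(2, 20, 25), matrix(-1, 20, 25))
  vru <- retinal_flow_field(vu, c(5, 5))
  expect_true(all(vru$vy == 0) && all(vru$vz == 0))
  # identity-like synthetic field: v(p) = p  =>  v_r(p) = p - g
  px <- matrix(rep(1:25, each = 20), 20); py <- matrix(rep(1:20, 25), 20)
  vi <- make_flow(px, py)
  vri <- retinal_flow_field(vi, c(7, 9))
  expect_equal(vri$vy[3, 12], 12 - 7)
  expect_equal(vri$vz[3, 12], 3 - 9)
  expect_error(retinal_flow_field(v, c(500, 2)), "outside")
})

test_that("flow direction is the full-quadrant angle, zero vectors invalid", {
  expect_equal(flow_direction(1, 0), 0)
  expect_equal(flow_direction(0, 1), pi / 2)
  expect_equal(flow_direction(-1, -1), -3 * pi / 4)
  expect_true(is.na(flow_direction(0, 0)))
})

test_that("lane-masked flow angle averages directions on the circle", {
  # all vectors straight down -> downward angle pi/2
  vd <- make_flow(matrix(0, 10, 10), matrix(3, 10, 10))
  mask <- matrix(TRUE, 10, 10)
  expect_equal(rof_angle(vd, mask)$angle, pi / 2)
  # split +-phi around down -> still down
  phi <- 0.7
  vy <- matrix(0, 10, 10); vz <- matrix(1, 10, 10)
  vy[, 1:5] <- sin(phi) * 3; vz[, 1:5] <- cos(phi) * 3
  vy[, 6:10] <- -sin(phi) * 3; vz[, 6:10] <- cos(phi) * 3
  expect_equal(rof_angle(make_flow(vy, vz), mask)$angle, pi / 2,
               tolerance = 1e-9)
  # all-zero masked vectors -> flagged invalid, not an error
  res <- rof_angle(make_flow(matrix(0, 10, 10), matrix(0, 10, 10)), mask)
  expect_false(res$valid)
  expect_true(is.na(res$angle))
})

test_that("gaze validity filtering matches confidence and border rules", {
  g <- data.frame(t = 1:5 / 10,
                  x = c(0.5, 0.15, 0.5, 0.5, 0.85),
                  y = c(0.5, 0.5, 0.5, 0.21, 0.5),
                  confidence = c(0.59, 0.9, 1.0, 0.8, 0.9),
                  valid = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  kept <- filter_gaze(g)
  expect_equal(kept$t, 0.3)           # only the centered high-confidence one
  expect_identical(filter_gaze(kept), kept)   # idempotent
})

test_that("detilt removes a constant bias via the straight-section median", {
  set.seed(4)
  t <- seq(0, 10, by = 0.1)
  base <- wrap_angle(rnorm(length(t), 0, 0.05))
  straight <- t < 5
  s0 <- rof_series(t, base)
  d0 <- detilt(s0, straight)
  expect_lt(abs(attr(d0, "bias")), 0.05)
  # add a constant offset: recovered bias shifts by the offset
  s1 <- rof_series(t, wrap_angle(base + 0.4))
  d1 <- detilt(s1, straight)
  expect_equal(attr(d1, "bias") - attr(d0, "bias"), 0.4, tolerance = 1e-9)
  expect_equal(d1$angle, d0$angle, tolerance = 1e-9)
  expect_error(detilt(rof_series(1:5, rep(0.1, 5)), rep(TRUE, 5)),
               "straight-section samples")
})

test_that("gaze headway is Euclidean distance over speed", {
  h <- gaze_headway(c(0, 0, 0), c(13, 0, 0), 13)
  expect_equal(h$t_h, 1.0)
  h2 <- gaze_headway(c(0, 0, 1.1), c(4, 0, 0), 5)
  expect_equal(h2$d_h, sqrt(16 + 1.21))
  expect_true(is.na(gaze_headway(c(0, 0, 1), c(1, 0, 0), 0)$t_h))
})

test_that("flow field and lane mask binary IO round-trips", {
  set.seed(6)
  v <- flow_field(matrix(rnorm(600), 20), matrix(rnorm(600), 20),
                  focal_length = 120, dt = 1 / 90)
  path <- tempfile(fileext = ".bin")
  write_flow_field(v, path)
  back <- read_flow_field(path)
  expect_equal(back$vy, v$vy, tolerance = 1e-6)   # float32 storage
  expect_equal(back$focal_length, 120)
  m <- matrix(runif(600) > 0.5, 20)
  mp <- tempfile(fileext = ".bin")
  write_lane_mask(m, mp)
  expect_identical(read_lane_mask(mp), m)
})
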