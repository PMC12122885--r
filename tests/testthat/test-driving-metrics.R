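test_that("heading deviation wraps into (-pi, pi]", {
  expect_equal(heading_deviation(0.3, 0.3), 0)
  expect_equal(heading_deviation(0.10, 0.05), 0.05)
  expect_equal(heading_deviation(-3.1, 3.1), -6.2 + 2 * pi, tolerance = 1e-12)
  set.seed(1)
  th <- heading_deviation(runif(200, -10, 10), runif(200, -10, 10))
  expect_true(all(th > -pi & th <= pi))
})

test_that("lateral displacement and velocity follow the road-frame forms", {
  expect_equal(lateral_displacement(0, 0), 0)
  expect_equal(lateral_displacement(0, -0.5), 0.5)
  lv <- lateral_velocity_approx(10, 0.1)
  expect_equal(lv$exact, 10 * sin(0.1))
  expect_equal(lv$exact, 0.99833, tolerance = 1e-5)
  expect_equal(lv$small_angle, 1.0)
  expect_lt(lateral_velocity_approx(10, -0.2)$exact, 0)
})

test_that("lateral acceleration reproduces the curve-bend load", {
  la <- lateral_acceleration(13, 30)
  expect_equal(la$ms2, 13^2 / 30)
  expect_equal(round(la$ms2, 2), 5.63)
  expect_equal(round(la$g_units, 2), 0.57)
  expect_equal(lateral_acceleration(0, 30)$ms2, 0)
  expect_error(lateral_acceleration(13, 0), "radius")
})

test_that("track geometry matches the S-track construction", {
  trk <- build_track(curve_diameter = 60)
  expect_equal(trk$curve_radius, 30)
  sec <- trk$sections
  expect_equal(sec$curvature[sec$label == "left_curve"], 1 / 30)
  expect_equal(sec$curvature[sec$label == "right_curve"], -1 / 30)
  expect_equal(sec$curvature[sec$type == "straight"], rep(0, 3))
  expect_equal(trk$total_length, sum(c(100, 20, 100)) + 2 * pi * 30)
  # projection identity: points laid on the centerline project back
  s <- seq(1, trk$total_length - 1, length.out = 41)
  p <- track_point(trk, s, 0)
  pr <- track_project(trk, p$x, p$y)
  expect_equal(pr$station, s, tolerance = 1e-8)
  expect_equal(pr$lateral, rep(0, 41), tolerance = 1e-8)
  # lateral offsets are recovered left-positive
  p2 <- track_point(trk, s, 0.8)
  pr2 <- track_project(trk, p2$x, p2$y)
  expect_equal(pr2$lateral, rep(0.8, 41), tolerance = 1e-8)
})

test_that("trial classification flags lane exits and control loss", {
  trk <- build_track()
  s <- seq(1, trk$total_length - 1, by = 2)
  mid <- track_point(trk, s, trk$lane_center_offset)
  ok_rec <- list(states = data.frame(t = seq_along(s) / 90, x = mid$x,
                                     y = mid$y, heading = mid$heading,
                                     speed = 13, vx = 13, vy = 0))
  expect_equal(classify_trial(ok_rec, trk), "success")
  # one sample fully outside the lane
  bad <- mid; i <- 40
  off <- track_point(trk, s[i], trk$lane_center_offset + trk$lane_width + 0.8)
  bad$x[i] <- off$x; bad$y[i] <- off$y
  bad_rec <- ok_rec; bad_rec$states$x <- bad$x; bad_rec$states$y <- bad$y
  expect_equal(classify_trial(bad_rec, trk), "failure")
  # slip: |v_y| twice v_x
  slip_rec <- ok_rec; slip_rec$states$vy[10] <- 2 * slip_rec$states$vx[10]
  expect_equal(classify_trial(slip_rec, trk), "failure")
})

test_that("roi extraction returns one half-open span per curve", {
  trk <- build_track()
  out <- cached_sim(seed = 31)
  spans <- roi_extract(out$rec, trk)
  expect_equal(nrow(spans), 2)
  expect_setequal(spans$label, c("left_curve", "right_curve"))
  st <- out$rec$states
  # entry sample included, exit sample excluded (half-open)
  sec <- trk$sections
  for (k in 1:2) {
    i <- which(sec$label == spans$label[k])
    lo <- sec$s0[i] + 0.15 * sec$length[i]
    hi <- sec$s0[i] + 0.85 * sec$length[i]
    expect_true(st$station[spans$start[k]] >= lo)
    expect_true(st$station[spans$end[k]] > hi ||
                  spans$end[k] == nrow(st) + 1L)
  }
  # straights only -> empty
  straight <- list(states = out$rec$states[out$rec$states$station < 90, ])
  expect_equal(nrow(roi_extract(straight, trk)), 0)
})

test_that("trial summary reproduces printed failure occurrences", {
  recs <- data.frame(
    outcome = c(rep("success", 53), rep("failure", 2),
                rep("success", 51), rep("failure", 4)),
    wheel_visible = c(rep(TRUE, 55), rep(FALSE, 55)))
  tab <- summarize_trials(recs)
  expect_equal(tab$failure_pct[tab$group == "visible"], 3.6)
  expect_equal(tab$failure_pct[tab$group == "not_visible"], 7.3)
  expect_equal(tab$failure_pct[tab$group == "total"], 5.5)
  expect_equal(tab$total, c(55, 55, 110))
  # all successes -> 0; order invariance of totals
  all_ok <- summarize_trials(data.frame(outcome = rep("success", 4),
                                        wheel_visible = c(TRUE, FALSE, TRUE, FALSE)))
  expect_equal(all_ok$failure_pct, c(0, 0, 0))
  shuf <- summarize_trials(recs[sample(nrow(recs)), ])
  expect_equal(shuf, tab)
})

test_that("correction count summary reproduces the printed table", {
  counts <- rbind(
    c(34, 21, 18, 19, 15, 20, 15, 23, 13, 15),
    c(33, 27, 28, 32, 31, 30, 30, 32, 29, 34),
    c(26, 36, 32, 22, 23, 30, 30, 30, 26, 24),
    c(27, 21, 24, 25, 31, 24, 21, 26, 26, 24),
    c(26, 23, 16, 18, 20, 16, 22, 23, 18, 26),
    c(26, 32, 25, 32, 21, 26, 22, 23, 25, 26),
    c(38, 37, 34, 27, 26, 24, 26, 24, 20, 27),
    c(28, 37, 38, 28, 22, 35, 32, 32, 26, 30))
  s <- summarize_corrections(counts, n_visible = 5)
  expect_equal(s$participant_totals,
               c(193, 306, 279, 249, 208, 258, 283, 308))
  expect_equal(s$total, 2084)
  expect_equal(round(s$overall_avg, 2), 26.05)
  expect_equal(round(s$per_trial_avg[1], 2), 29.75)
  # the table prints half-up roundings of 26.975 and 25.125
  expect_lt(abs(s$visible_avg - 26.98), 0.01)
  expect_lt(abs(s$nonvisible_avg - 25.13), 0.01)
  empty <- summarize_corrections(matrix(numeric(), 0, 0))
  expect_equal(empty$total, 0)
})

test_that("log-normal correction-angle fit recovers generator parameters", {
  set.seed(9)
  d <- exp(rnorm(5000, 0.08, sqrt(0.66)))
  fit <- fit_correction_angle_distribution(d)
  expect_lt(abs(fit$mu - 0.08), 0.05)
  expect_lt(abs(fit$sigma2 - 0.66), 0.05)
  same <- fit_correction_angle_distribution(rep(0.4, 10))
  expect_equal(same$mu, log(0.4))
  expect_equal(same$sigma2, 0)
  expect_error(fit_correction_angle_distribution(c(0.1, 0)), "> 0")
})
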