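test_that("pairing reads the cue at lagged onsets and drops misses", {
  set <- correction_set(c(1, 1), c(1 + 2 * 0.1, 2 + 2 * 0.1), c(0.1, 0.1))
  # onsets at 1.0 and 2.0
  ramp <- new_signal(seq(0, 3, by = 0.01), dt = 0.01)   # cue(t) = t
  p0 <- pair_corrections_with_stimulus(set, ramp, tau = 0.5)
  expect_equal(p0$stimulus, c(0.5, 1.5), tolerance = 1e-9)
  expect_equal(p0$response, travel_distance(set))
  const <- new_signal(rep(1, 301), dt = 0.01)
  expect_equal(pair_corrections_with_stimulus(set, const, 0)$stimulus, c(1, 1))
  # onset before cue start at this tau -> dropped
  p2 <- pair_corrections_with_stimulus(set, ramp, tau = 1.5)
  expect_equal(nrow(p2), 1)
  expect_error(pair_corrections_with_stimulus(set, ramp, tau = 10), "dropped")
  # alternative onset definitions
  pm <- pair_corrections_with_stimulus(set, ramp, 0, onset_def = "mode")
  expect_equal(pm$stimulus, set$mu, tolerance = 1e-9)
})

test_that("zncc is the Pearson coefficient with its guard rails", {
  p <- data.frame(response = c(1, 2, 3, 4), stimulus = c(1, 2, 3, 4))
  expect_equal(zncc(p), 1)
  expect_equal(zncc(data.frame(response = 1:4, stimulus = -(1:4))), -1)
  set.seed(10)
  big <- data.frame(response = rnorm(1000), stimulus = rnorm(1000))
  expect_lt(abs(zncc(big)), 0.1)
  expect_error(zncc(p[1:2, ]), "at least 3")
  expect_error(zncc(data.frame(response = c(1, 1, 1), stimulus = 1:3)),
               "constant")
  # invariance to positive affine rescaling
  expect_equal(zncc(data.frame(response = 3 * big$response + 2,
                               stimulus = 0.5 * big$stimulus - 1)),
               zncc(big), tolerance = 1e-12)
})

test_that("latency scan recovers a constructed lag exactly", {
  set.seed(11)
  n <- 60
  mu <- seq(1, 30, length.out = n)
  sig <- runif(n, 0.08, 0.16)
  a <- rnorm(n, 0, 0.8)
  set <- correction_set(a, mu, sig)
  # place the response values into the cue exactly 0.3 s before each onset
  cue_t <- seq(0, 31, by = 1 / 90)
  cue_v <- rep(0, length(cue_t))
  t_on <- set$mu - 2 * set$sigma
  idx <- round((t_on - 0.3) * 90) + 1
  cue_v[idx] <- travel_distance(set)
  cue <- new_signal(cue_v, dt = 1 / 90)
  sc <- latency_scan(set, cue, grid_step = 1 / 90)
  expect_equal(sc$tau_star, 27 / 90, tolerance = 1e-9)  # 0.3 s
  expect_true(all(sc$rho <= 1 & sc$rho >= -1, na.rm = TRUE))
  # independent cue: no spurious strong peak at n large
  set.seed(12)
  n2 <- 600
  set2 <- correction_set(rnorm(n2, 0, 0.5), seq(2, 120, length.out = n2),
                         runif(n2, 0.08, 0.16))
  noise_cue <- new_signal(rnorm(123 * 90), dt = 1 / 90)
  sc2 <- latency_scan(set2, noise_cue, grid_step = 0.05)
  expect_lt(max(sc2$rho, na.rm = TRUE), 0.2)
})

test_that("rank scans agree with Pearson through monotone maps", {
  set.seed(13)
  n <- 80
  # grid-aligned onsets so the lagged cue reads are exact interpolation nodes
  t_on <- round(seq(1, 40, length.out = n) * 90) / 90
  sig <- runif(n, 0.08, 0.16)
  set <- correction_set(abs(rnorm(n, 1, 0.3)), t_on + 2 * sig, sig)
  cue_t <- seq(0, 41, by = 1 / 90)
  # cue = cube root of response placed at t_on - 0.2: monotone nonlinear
  cue_v <- approx(t_on - 0.2, travel_distance(set)^(1 / 3), xout = cue_t,
                  rule = 2)$y
  cue <- new_signal(cue_v, dt = 1 / 90)
  sp <- rank_correlation_scan(set, cue, grid_step = 0.1, method = "spearman")
  expect_equal(max(sp$rho, na.rm = TRUE), 1, tolerance = 1e-9)
  expect_equal(sp$tau_star, 0.2, tolerance = 1e-9)
  kd <- rank_correlation_scan(set, cue, grid_step = 0.1, method = "kendall")
  expect_equal(kd$tau_star, 0.2, tolerance = 1e-9)
  # Pearson scan shares the rank scans' argmax on the same construction
  pe <- latency_scan(set, cue, grid_step = 0.1)
  expect_equal(pe$tau_star, 0.2, tolerance = 1e-9)
})

test_that("recentering removes independent per-curve offsets", {
  t <- seq(0.1, 10, by = 0.1)
  labels <- rep(c("left_curve", "right_curve"), each = length(t) / 2)
  ang <- ifelse(labels == "left_curve", 0.5, -0.8)
  s <- rof_series(t, ang)
  out <- recenter_by_curve(s, labels)
  expect_equal(out$angle, rep(0, length(t)), tolerance = 1e-9)
  cen <- attr(out, "centers")
  expect_equal(cen$left_curve, 0.5, tolerance = 1e-9)
  expect_equal(cen$right_curve, -0.8, tolerance = 1e-9)
  expect_error(recenter_by_curve(s, rep("left_curve", length(t))),
               "right_curve")
})

test_that("pseudo-Huber regression resists outliers and limits to OLS", {
  set.seed(14)
  x <- runif(200, -2, 2)
  y <- 2 * x + 1
  p <- data.frame(response = y, stimulus = x)
  fit <- robust_linreg(p, huber_delta = 1)
  expect_equal(fit$slope, 2, tolerance = 1e-6)
  expect_equal(fit$intercept, 1, tolerance = 1e-6)
  # 5 % gross outliers
  yo <- y; bad <- sample(200, 10); yo[bad] <- yo[bad] + 40
  po <- data.frame(response = yo, stimulus = x)
  rob <- robust_linreg(po, huber_delta = 0.5)
  ols <- robust_linreg(po, huber_delta = Inf)
  expect_lt(abs(rob$slope - 2), abs(ols$slope - 2))
  # huber_delta -> Inf limit matches least squares
  almost <- robust_linreg(po, huber_delta = 1e4)
  expect_equal(almost$slope, ols$slope, tolerance = 1e-4)
  expect_error(robust_linreg(data.frame(response = 1:3,
                                        stimulus = rep(1, 3))), "degenerate")
})
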