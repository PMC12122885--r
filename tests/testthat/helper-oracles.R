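# Independent numerical oracles used to freeze expected values.

# composite Simpson quadrature on [a, b]
simpson <- function(f, a, b, n = 2000L) {
  if (n %% 2L == 1L) n <- n + 1L
  x <- seq(a, b, length.out = n + 1L)
  y <- f(x)
  h <- (b - a) / n
  h / 3 * (y[1] + y[n + 1] + 4 * sum(y[seq(2, n, by = 2)]) +
             2 * sum(y[seq(3, n - 1, by = 2)]))
}

# quadrature oracle for the travel distance of one Gaussian correction
travel_quadrature <- function(a, mu, sigma) {
  simpson(function(t) a * exp(-(t - mu)^2 / (2 * sigma^2)),
          mu - 8 * sigma, mu + 8 * sigma)
}

# shared simulated trials (expensive; memoised per test run)
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(seed, tau_d = 0.15, track = NULL) {
  key <- sprintf("s%d_t%g", seed, tau_d)
  if (is.null(.sim_cache[[key]])) {
    trk <- if (is.null(track)) build_track() else track
    .sim_cache[[key]] <- simulate_drive(
      trk, driver_params(seed = seed,
                         latency = latency_components(tau_d, 0, 0)))
  }
  .sim_cache[[key]]
}

# random well-separated correction sets for decomposition oracles
random_truth <- function(N, sig_lo = 0.0707, sig_hi = 0.1732) {
  sig <- runif(N, sig_lo, sig_hi)
  mu <- numeric(N)
  mu[1] <- runif(1, 0.5, 0.8)
  if (N > 1) {
    for (j in 2:N) mu[j] <- mu[j - 1] + 2 * sig_hi + runif(1, 0, 0.3)
  }
  a <- runif(N, 0.4, 1.5) * sample(c(-1, 1), N, replace = TRUE)
  correction_set(a, mu, sig)
}
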