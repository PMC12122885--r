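#' Configuration for ballistic-correction decomposition
#'
#' Settings for the penalized particle swarm decomposition of a steering
#' rate signal into constituent Gaussian ballistic corrections. The fitness
#' of a candidate set with N corrections over a window `(t0, t1)` is
#' \deqn{\max(N,1)^\alpha / (t_1-t_0) \int_{t_0}^{t_1} |z(t) - \sum \dot\delta_b(t)| dt}
#' (integral by trapezoid on the signal grid). The `max(N,1)` guard keeps
#' the empty model from being a trivial global optimum while preserving the
#' intent of the complexity penalty.
#'
#' @param alpha complexity penalty exponent (> 0). Default 1: linear
#'   penalty in the number of corrections.
#' @param n_max maximum number of corrections per window.
#' @param sigma_bounds allowed rate-parameter interval, seconds. Default is
#'   the empirical steering interval `c(0.0707, 0.1732)`.
#' @param a_bound maximum `|a|` in rad/s; `NULL` means 4x the peak `|z|`.
#' @param swarm_size,iterations,inertia,cognitive_coeff,social_coeff PSO
#'   hyperparameters (global-best topology, reflecting bounds). Defaults
#'   are the standard constriction-style coefficients.
#' @param seed integer RNG seed; every PSO run derives its own stream from
#'   it, so results are bit-reproducible.
#' @param prune_threshold corrections with `|travel_distance|` below this
#'   (radians) are dropped from the selected model.
#' @param rate_threshold `segment_signal` quiet threshold, rad/s.
#' @param max_window maximum window length in seconds before splitting.
#' @param patience PSO iterations without improvement before early stop.
#' @param order_patience consecutive non-improving model orders before the
#'   order search stops. The default (`NULL` = `n_max + 1`) searches every
#'   order exhaustively: the penalized fitness is not monotone in N for
#'   dense correction trains, so greedy stopping can strand the search
#'   below the true order. Set small only for quick exploratory fits.
#' @param polish logical; refine each PSO optimum with a deterministic
#'   Nelder-Mead polish on the same fitness.
#' @return a `sf_decomp_config` list.
#' @export
decomposition_config <- function(alpha = 1, n_max = 10,
                                 sigma_bounds = c(0.0707, 0.1732),
                                 a_bound = NULL,
                                 swarm_size = 60, iterations = 400,
                                 inertia = 0.729,
                                 cognitive_coeff = 1.49445,
                                 social_coeff = 1.49445,
                                 seed = 1, prune_threshold = 0.005,
                                 rate_threshold = 0.05, max_window = 4,
                                 patience = 60, order_patience = NULL,
                                 polish = TRUE) {
  stopifnot(alpha > 0, n_max >= 0, length(sigma_bounds) == 2,
            sigma_bounds[1] > 0, sigma_bounds[2] > sigma_bounds[1],
            swarm_size >= 10, iterations >= 1, is.finite(seed))
  structure(list(alpha = alpha, n_max = as.integer(n_max),
                 sigma_bounds = as.numeric(sigma_bounds),
                 a_bound = a_bound, swarm_size = as.integer(swarm_size),
                 iterations = as.integer(iterations), inertia = inertia,
                 cognitive_coeff = cognitive_coeff,
                 social_coeff = social_coeff, seed = as.integer(seed),
                 prune_threshold = prune_threshold,
                 rate_threshold = rate_threshold, max_window = max_window,
                 patience = as.integer(patience),
                 order_patience = as.integer(
                   if (is.null(order_patience)) n_max + 1L else order_patience),
                 polish = isTRUE(polish)),
            class = "sf_decomp_config")
}

#' Penalized L1 fitness of a candidate correction set
#'
#' @param candidate an `sf_corrections` set.
#' @param z observed steering-rate `sf_signal`.
#' @param window `c(t0, t1)` in seconds, within the domain of `z`.
#' @param alpha complexity penalty exponent.
#' @return non-negative fitness value.
#' @export
fitness <- function(candidate, z, window, alpha = 1) {
  stopifnot(inherits(candidate, "sf_corrections"), inherits(z, "sf_signal"),
            length(window) == 2)
  if (window[2] <= window[1]) stop("empty window: t1 must exceed t0")
  par <- c(candidate$a, candidate$mu, candidate$sigma)
  fitness_window_cpp(signal_time(z), z$values, window[1], window[2],
                     as.numeric(par), alpha)
}

#' Split a steering-rate signal into active windows
#'
#' Splits at quiet runs (`|z| < rate_threshold`) lasting at least
#' `4 * sigma_low` (one minimum-duration correction). Windows longer than
#' `max_window` are recursively bisected at their quietest interior sample.
#' Each window is padded by `2 * sigma_low` (clipped to the signal domain
#' and to its neighbours) so threshold-clipped correction tails stay inside.
#'
#' @param z an `sf_signal`.
#' @param rate_threshold quiet threshold, rad/s.
#' @param max_window maximum window length, seconds (`Inf` to disable).
#' @param sigma_low minimum correction rate parameter, seconds.
#' @return data frame with columns `t0`, `t1` (half-open windows), possibly
#'   zero rows.
#' @export
segment_signal <- function(z, rate_threshold = 0.05, max_window = 4,
                           sigma_low = 0.0707) {
  stopifnot(inherits(z, "sf_signal"))
  tt <- signal_time(z)
  active <- abs(z$values) >= rate_threshold
  if (!any(active)) {
    return(data.frame(t0 = numeric(), t1 = numeric()))
  }
  min_quiet <- max(1L, ceiling(4 * sigma_low / z$dt))
  # group active samples: a new group starts after a long-enough quiet run
  idx <- which(active)
  grp <- cumsum(c(1L, as.integer(diff(idx) > min_quiet)))
  spans <- do.call(rbind, lapply(split(idx, grp), function(ix) {
    c(i0 = min(ix), i1 = max(ix))
  }))
  # pad by 2*sigma_low, clip to domain and to neighbouring spans
  pad <- 2 * sigma_low
  t0s <- pmax(tt[spans[, "i0"]] - pad, tt[1])
  t1s <- pmin(tt[spans[, "i1"]] + z$dt + pad, tt[length(tt)])
  if (length(t0s) > 1) {
    mids <- (t1s[-length(t1s)] + t0s[-1]) / 2
    t1s[-length(t1s)] <- pmin(t1s[-length(t1s)], mids)
    t0s[-1] <- pmax(t0s[-1], mids)
  }
  out <- data.frame(t0 = t0s, t1 = t1s)
  # bisect over-long windows at the quietest interior sample
  split_long <- function(w) {
    if (w$t1 - w$t0 <= max_window) return(w)
    sel <- which(tt >= w$t0 & tt < w$t1)
    interior <- sel[tt[sel] > w$t0 + 4 * sigma_low & tt[sel] < w$t1 - 4 * sigma_low]
    if (length(interior) == 0) return(w)
    cut <- tt[interior[which.min(abs(z$values[interior]))]]
    rbind(split_long(data.frame(t0 = w$t0, t1 = cut)),
          split_long(data.frame(t0 = cut, t1 = w$t1)))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(out)), function(i) split_long(out[i, ])))
  rownames(out) <- NULL
  out
}

# deterministic per-(window, order) seed derived from the master seed
derive_seed <- function(seed, window_index, order) {
  (((seed %% 1048576L) + 1L) * 1021L + 131L * window_index + 7L * order) %% 2147483647L
}

# Nelder-Mead polish of a PSO optimum on the same C++ fitness; parameters
# are clamped into bounds with a quadratic penalty to keep the simplex in.
polish_fit <- function(par, tt, zz, t0, t1, alpha, lower, upper) {
  if (length(par) == 0) return(list(par = par,
    fitness = fitness_window_cpp(tt, zz, t0, t1, numeric(), alpha)))
  fn <- function(p) {
    pc <- pmin(pmax(p, lower), upper)
    pen <- sum((p - pc)^2)
    fitness_window_cpp(tt, zz, t0, t1, pc, alpha) + 1e3 * pen
  }
  o <- optim(par, fn, method = "Nelder-Mead",
             control = list(maxit = 3000, reltol = 1e-12))
  p <- pmin(pmax(o$par, lower), upper)
  list(par = p, fitness = fitness_window_cpp(tt, zz, t0, t1, p, alpha))
}

decompose_window <- function(z, w, config, window_index) {
  tt <- signal_time(z); zz <- z$values
  sel <- tt >= w[1] & tt <= w[2]
  a_bound <- config$a_bound
  if (is.null(a_bound)) a_bound <- 4 * max(abs(zz[sel]), 1e-6)
  sig_lo <- config$sigma_bounds[1]; sig_hi <- config$sigma_bounds[2]
  mu_lo <- w[1] - 2 * sig_hi; mu_hi <- w[2] + 2 * sig_hi

  best <- NULL; best_N <- -1L; stall <- 0L
  prev_par <- numeric(0)
  sig_mid <- sqrt(sig_lo * sig_hi)
  for (N in 0:config$n_max) {
    lower <- c(rep(-a_bound, N), rep(mu_lo, N), rep(sig_lo, N))
    upper <- c(rep(a_bound, N), rep(mu_hi, N), rep(sig_hi, N))
    # greedy warm start: previous order's optimum plus one component at the
    # peak of its residual (keeps PSO from stalling below the true order)
    init <- NULL
    if (N > 0 && length(prev_par) == 3 * (N - 1)) {
      M <- N - 1L
      resid <- zz - superpose_eval_cpp(tt, prev_par[seq_len(M)],
                                       prev_par[M + seq_len(M)],
                                       prev_par[2 * M + seq_len(M)])
      insel <- which(sel)
      pk <- insel[which.max(abs(resid[insel]))]
      cand <- c(prev_par[seq_len(M)], resid[pk],
                prev_par[M + seq_len(M)], tt[pk],
                prev_par[2 * M + seq_len(M)], sig_mid)
      init <- matrix(cand, nrow = 1)
    }
    fit <- pso_fit_cpp(tt, zz, w[1], w[2], N, config$alpha, lower, upper,
                       config$swarm_size, config$iterations, config$inertia,
                       config$cognitive_coeff, config$social_coeff,
                       config$patience, 1e-10,
                       derive_seed(config$seed, window_index, N), init)
    if (config$polish) {
      pol <- polish_fit(fit$par, tt, zz, w[1], w[2], config$alpha, lower, upper)
      fit$par <- pol$par; fit$fitness <- pol$fitness
    }
    prev_par <- fit$par
    if (is.null(best) || fit$fitness < best$fitness) {
      best <- fit; best_N <- N; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$order_patience) break
    }
  }
  N <- length(best$par) / 3
  set <- correction_set(best$par[seq_len(N)],
                        best$par[N + seq_len(N)],
                        best$par[2 * N + seq_len(N)])
  list(set = set, fitness = best$fitness, n = N)
}

#' Decompose a steering-rate signal into ballistic corrections
#'
#' Segments the signal into active windows, runs a seeded particle swarm
#' per window for each candidate model order `N = 0..n_max`, keeps the
#' order with minimal penalized fitness, and prunes corrections whose
#' absolute travel distance falls below `prune_threshold`. Deterministic
#' given `config$seed`.
#'
#' @param z observed steering-rate `sf_signal` (uniform, finite).
#' @param config a [decomposition_config()].
#' @return an `sf_fit` list: `corrections` (`sf_corrections`), `fitness`
#'   (penalized fitness of the merged set over the full signal span),
#'   `mean_abs_residual` (rad/s), `window` (`c(t0, t1)` of the signal) and
#'   `windows` (the per-window segmentation with per-window fitness).
#' @export
decompose <- function(z, config = decomposition_config()) {
  stopifnot(inherits(z, "sf_signal"), inherits(config, "sf_decomp_config"))
  wins <- segment_signal(z, config$rate_threshold, config$max_window,
                         config$sigma_bounds[1])
  sets <- list(); wfit <- numeric(nrow(wins))
  if (nrow(wins) > 0) {
    # windows are fitted in time order against the residual of everything
    # already modelled, so corrections straddling a window split are fitted
    # once instead of twice (residual carry-over)
    tt_all <- signal_time(z)
    z_res <- z
    for (i in seq_len(nrow(wins))) {
      r <- decompose_window(z_res, c(wins$t0[i], wins$t1[i]), config, i)
      sets[[i]] <- r$set; wfit[i] <- r$fitness
      if (nrow(r$set) > 0) {
        z_res$values <- z_res$values -
          superpose_eval_cpp(tt_all, r$set$a, r$set$mu, r$set$sigma)
      }
    }
  }
  merged <- if (length(sets)) {
    do.call(rbind, lapply(sets, as.data.frame))
  } else {
    data.frame(a = numeric(), mu = numeric(), sigma = numeric())
  }
  set <- correction_set(merged$a, merged$mu, merged$sigma)
  keep <- abs(travel_distance(set)) >= config$prune_threshold
  set <- correction_set(set$a[keep], set$mu[keep], set$sigma[keep])

  tt <- signal_time(z)
  window <- c(tt[1], tt[length(tt)])
  resid <- z$values - superpose(set, tt)
  fit_total <- if (length(tt) >= 2) {
    fitness(set, z, window, config$alpha)
  } else 0
  structure(list(corrections = set, fitness = fit_total,
                 mean_abs_residual = mean(abs(resid)), window = window,
                 windows = cbind(wins, fitness = wfit)),
            class = "sf_fit")
}

#' @export
print.sf_fit <- function(x, ...) {
  cat(sprintf("<sf_fit> %d corrections over [%.3g, %.3g]s, fitness %.5g, mean |resid| %.5g rad/s\n",
              nrow(x$corrections), x$window[1], x$window[2], x$fitness,
              x$mean_abs_residual))
  invisible(x)
}
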