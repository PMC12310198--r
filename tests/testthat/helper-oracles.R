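# Independent oracles and small fixture builders shared across tests.

# Pure-R Gillespie reference built from the exported primitives; consumes
# uniforms in the same (r1, r2) order as the compiled core, so event streams
# must agree bit-for-bit for a given RNG stream.
reference_worm_events <- function(params, initial_m = params$m0,
                                  seed = params$seed) {
  set.seed(seed)
  t <- 0
  m <- initial_m
  ev <- numeric(0)
  repeat {
    pr <- compute_propensities(m, params)
    if (pr$a0 <= 0) break
    r1 <- runif(1)
    while (r1 == 0) r1 <- runif(1)
    t <- t + draw_interval(pr$a0, r1)
    if (t > params$duration) break
    if (select_event(pr, runif(1)) == 1L) ev <- c(ev, t) else m <- m - 1L
  }
  ev
}

# Brute-force two-segment changepoint oracle: every admissible split, a
# from-scratch lm() per segment, no shared code with two_segment_fit().
brute_force_two_segment <- function(curve, min_seg = 2) {
  df <- as.data.frame(curve)
  x <- df$time_min
  y <- df$omega
  n <- length(x)
  best <- NULL
  for (k in 3:(n - 1)) {
    if (x[k - 1] - x[1] < min_seg || x[n] - x[k] < min_seg) next
    f1 <- lm(y ~ x, data = data.frame(x = x[1:(k - 1)], y = y[1:(k - 1)]))
    f2 <- lm(y ~ x, data = data.frame(x = x[k:n], y = y[k:n]))
    rss <- sum(residuals(f1)^2) + sum(residuals(f2)^2)
    if (is.null(best) || rss < best$rss_total - 1e-12) {
      best <- list(split_index = k, s1 = unname(coef(f1)[2]),
                   s2 = unname(coef(f2)[2]), b1 = unname(coef(f1)[1]),
                   b2 = unname(coef(f2)[1]), rss_total = rss)
    }
  }
  best
}

# Random cumulative-count curve: piecewise-ish Poisson event stream.
random_cumulative_curve <- function(duration = 45, grid_step = 0.5,
                                    mean_events = 40) {
  n_ev <- rpois(1, mean_events)
  times <- sort(runif(n_ev, 0, duration))
  cumulative_curve(times, grid_step = grid_step,
                   total_duration = duration)
}

# Tiny deterministic population used across IO/pipeline tests.
tiny_population <- function(n_worms = 5, seed = 404, duration = 20) {
  simulate_population(sim_params(n_worms = n_worms, seed = seed,
                                 duration = duration))
}
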