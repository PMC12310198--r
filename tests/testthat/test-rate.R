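test_that("rolling rate counts events in centred, renormalised windows", {
  rc <- rolling_rate(c(10, 10.5, 11), window = 2, grid_step = 0.5,
                     total_duration = 45)
  expect_equal(rc$rate[rc$time_min == 10.5], 3 / 2)
  # window [9.5, 11.5) at t = 10.5 holds all three events; at t = 12 the
  # window [11, 13) holds only the event at 11
  expect_equal(rc$rate[rc$time_min == 12], 1 / 2)

  # boundary: half-window truncated to [0, 1), renormalised by length 1
  rb <- rolling_rate(0, window = 2, total_duration = 45)
  expect_equal(rb$rate[rb$time_min == 0], 1)

  # empty trajectory: a valid all-zero curve
  r0 <- rolling_rate(numeric(0), total_duration = 45)
  expect_true(all(r0$rate == 0))
  expect_true(all(diff(r0$time_min) > 0))
})

test_that("population rate is the pointwise mean/SD and is order-invariant", {
  # two worms engineered to have rates 1 and 2 at t = 10 (window [9, 11))
  w1 <- c(9.2, 10.1)
  w2 <- c(9.1, 9.6, 10.2, 10.8)
  rc <- population_rate(list(w1, w2), window = 2, total_duration = 20)
  expect_equal(rc$rate[rc$time_min == 10], 1.5)
  expect_equal(rc$sd[rc$time_min == 10], sd(c(1, 2)))

  # identical worms: zero SD everywhere
  same <- population_rate(list(w1, w1, w1), total_duration = 20)
  expect_true(all(same$sd == 0))

  swapped <- population_rate(list(w2, w1), window = 2, total_duration = 20)
  expect_equal(rc$rate, swapped$rate)
  expect_equal(rc$sd, swapped$sd)
})

test_that("rate curve integrates back to the event count", {
  pop <- simulate_population(sim_params(n_worms = 10, seed = 56))
  busy <- Filter(function(tr) length(tr$event_times) >= 20, pop)
  expect_gte(length(busy), 1)
  for (tr in busy) {
    rc <- rolling_rate(tr)
    integral <- sum(diff(rc$time_min) *
                    (head(rc$rate, -1) + tail(rc$rate, -1)) / 2)
    expect_equal(integral, length(tr$event_times), tolerance = 0.05)
  }
})

test_that("population mean curve tracks alpha exp(-gamma t) + beta", {
  p <- sim_params(n_worms = 500, seed = 61)
  rc <- population_rate(simulate_population(p, record_m = FALSE))
  for (t in seq(3, 43, length.out = 10)) {
    i <- which.min(abs(rc$time_min - t))
    expected <- p$alpha * exp(-p$gamma * rc$time_min[i]) + p$beta
    expect_lt(abs(rc$rate[i] - expected),
              3 * rc$sd[i] / sqrt(attr(rc, "n_worms")))
  }
})

test_that("decay fit recovers exact curves and degenerates gracefully", {
  t <- seq(0, 45, 0.5)
  exact <- data.frame(time_min = t, rate = 1.49 * exp(-0.11 * t) + 0.1937)
  fit <- fit_decay(exact)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), c(1.49, 0.1937, 0.11), tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)
  expect_equal(predict(fit, 0), 1.49 + 0.1937, tolerance = 1e-6)

  # another triple, far from the defaults
  exact2 <- data.frame(time_min = t, rate = 0.3 * exp(-0.04 * t) + 0.9)
  expect_equal(unname(coef(fit_decay(exact2))), c(0.3, 0.9, 0.04),
               tolerance = 1e-5)

  # constant curve: amplitude ~0, baseline ~c (gamma unidentifiable)
  flat <- fit_decay(data.frame(time_min = t, rate = rep(0.7, length(t))))
  cf <- coef(flat)
  expect_lt(cf["alpha"], 1e-4)
  expect_equal(unname(cf["beta"]), 0.7, tolerance = 1e-3)

  expect_error(fit_decay(exact[1:3, ]), "at least 4")
})

test_that("fitted populations round-trip the generating parameters", {
  p <- sim_params(n_worms = 400, seed = 77)
  fit <- fit_decay(population_rate(simulate_population(p, record_m = FALSE)))
  cf <- coef(fit)
  expect_equal(unname(cf["alpha"]), p$alpha, tolerance = 0.1)
  expect_equal(unname(cf["gamma"]), p$gamma, tolerance = 0.15)
  expect_equal(unname(cf["beta"]), p$beta, tolerance = 0.3)
})

test_that("half-life is log(2)/gamma", {
  expect_equal(half_life(log(2)), 1)
  expect_equal(half_life(0.07), 9.902, tolerance = 1e-4)
  expect_equal(half_life(0.11), 6.3013, tolerance = 1e-4)
  expect_error(half_life(0), "undefined")
  expect_error(half_life(-1), "undefined")

  t <- seq(0, 45, 0.5)
  fit <- fit_decay(data.frame(time_min = t,
                              rate = 2 * exp(-0.07 * t) + 0.1))
  expect_equal(half_life(fit), log(2) / 0.07, tolerance = 1e-4)
})

test_that("decay_fit methods are coherent", {
  t <- seq(0, 45, 0.5)
  set.seed(3)
  noisy <- data.frame(time_min = t,
                      rate = pmax(1.49 * exp(-0.11 * t) + 0.1937 +
                                  rnorm(length(t), 0, 0.02), 0))
  fit <- fit_decay(noisy)
  expect_equal(fitted(fit) + residuals(fit), noisy$rate)
  expect_equal(sum(residuals(fit)^2), fit$rss)
  s <- summary(fit)
  expect_equal(s$coefficients, coef(fit))
  pop <- simulate(fit, seed = 4, n_worms = 3, duration = 5)
  expect_s3_class(pop, "worm_population")
  expect_length(pop, 3)
})
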