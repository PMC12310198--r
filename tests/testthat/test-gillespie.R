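test_that("propensities follow a1 = (alpha/M0) M + beta, a2 = gamma M", {
  p <- sim_params()  # alpha 1.49, beta 0.1937, gamma 0.11, M0 1000
  pr <- compute_propensities(1000, p)
  expect_equal(pr$a1, 1.6837)
  expect_equal(pr$a2, 110)
  expect_equal(pr$a0, 111.6837)
  expect_identical(pr$a0, pr$a1 + pr$a2)

  # decay exhausted: only the baseline remains
  pr0 <- compute_propensities(0, p)
  expect_equal(pr0$a1, p$beta)
  expect_equal(pr0$a2, 0)

  # linear in M
  ph <- compute_propensities(
    500, sim_params(alpha = 2, beta = 0, gamma = 0.1, m0 = 1000))
  expect_equal(ph$a1, 1.0)
  expect_equal(ph$a2, 50)

  # constant mode: time-invariant total rate alpha + beta, decay off
  pc <- compute_propensities(0, sim_params(alpha = 1.5, beta = 0,
                                           mode = "constant"))
  expect_equal(pc$a1, 1.5)
  expect_equal(pc$a2, 0)

  expect_error(
    compute_propensities(3, sim_params(m0 = 0, alpha = 1)),
    "invalid configuration")
})

test_that("waiting times and event selection follow the SSA rules", {
  expect_equal(draw_interval(5, 1), 0)
  expect_equal(draw_interval(2, exp(-1)), 0.5)
  expect_equal(draw_interval(4, 0.25), log(4) / 4)
  expect_error(draw_interval(0, 0.5), "positive")
  expect_error(draw_interval(2, 0), "resample")

  p <- sim_params(alpha = 1, beta = 0, gamma = 3 / 1000)
  pr <- compute_propensities(1000, p)  # a1 = 1, a2 = 3
  expect_identical(select_event(pr, 0), 1L)
  expect_identical(select_event(pr, 0.5), 2L)   # 0.5 * 4 = 2 > a1
  expect_identical(select_event(pr, 0.25), 1L)  # boundary: 1 <= a1

  # ensemble: channel 1 fires with probability a1/a0 (here 10%)
  p10 <- sim_params(alpha = 1, beta = 0, gamma = 9 / 1000)
  pr10 <- compute_propensities(1000, p10)
  expect_equal(pr10$a1 / pr10$a0, 0.1)
  set.seed(20)
  picks <- vapply(runif(2e4), function(r2) select_event(pr10, r2),
                  integer(1))
  expect_equal(mean(picks == 1L), 0.1, tolerance = 0.1)
})

test_that("initial M inverts the target initial rate", {
  p <- sim_params()
  expect_identical(assign_initial_m(p$alpha + p$beta, p), p$m0)
  expect_identical(assign_initial_m(p$beta, p), 0L)
  expect_identical(assign_initial_m(1.0, p), 541L)
  # below-baseline draws clamp to zero, above-amplitude to M0
  expect_identical(assign_initial_m(0.01, p), 0L)
  expect_identical(assign_initial_m(99, p), p$m0)
  # with continuous M the propensity would reproduce r; rounding costs at
  # most alpha / (2 M0)
  r <- 0.737
  a1 <- compute_propensities(assign_initial_m(r, p), p)$a1
  expect_lt(abs(a1 - r), p$alpha / (2 * p$m0) + 1e-12)
})

test_that("single-worm trajectories satisfy the structural invariants", {
  p <- sim_params(n_worms = 1, seed = 33)
  tr <- simulate_worm(p)
  expect_true(all(diff(tr$event_times) > 0))
  expect_true(all(tr$event_times >= 0 & tr$event_times <= p$duration))
  expect_identical(tr$m_path$M[1], p$m0)
  expect_true(all(diff(tr$m_path$M) == -1L))
  expect_true(all(tr$m_path$M >= 0))

  # null process: no channel can fire
  null <- simulate_worm(sim_params(alpha = 0, beta = 0, gamma = 0,
                                   n_worms = 1))
  expect_length(null$event_times, 0)
  expect_identical(nrow(null$m_path), 1L)
})

test_that("compiled core and primitive-built R reference agree bit-for-bit", {
  for (case in list(sim_params(n_worms = 1, m0 = 50, duration = 20),
                    sim_params(alpha = 1.5, beta = 0, mode = "constant",
                               n_worms = 1, duration = 20))) {
    for (seed in c(1, 99, 2024)) {
      expect_identical(
        simulate_worm(case, seed = seed)$event_times,
        reference_worm_events(case, seed = seed))
    }
  }
})

test_that("identical seeds give identical populations; streams are stable", {
  p <- sim_params(n_worms = 8, seed = 5, duration = 15)
  a <- simulate_population(p)
  b <- simulate_population(p)
  expect_identical(as.data.frame(a), as.data.frame(b))

  # enlarging the population must not reshuffle earlier worms
  p2 <- p; p2$n_worms <- 16L
  big <- simulate_population(p2)
  for (i in 1:8) {
    expect_identical(a[[i]]$event_times, big[[i]]$event_times)
  }
})

test_that("constant-mode event counts are Poisson(a T)", {
  # a = 1.5/min over 40 min: mean = var = 60
  p <- sim_params(alpha = 1.5, beta = 0, mode = "constant", duration = 40,
                  n_worms = 3000, seed = 8)
  cnt <- vapply(simulate_population(p, record_m = FALSE),
                function(tr) length(tr$event_times), integer(1))
  se_mean <- sd(cnt) / sqrt(length(cnt))
  expect_lt(abs(mean(cnt) - 60), 3 * se_mean)
  expect_equal(var(cnt), 60, tolerance = 0.1)
})

test_that("constant-mode inter-event intervals are exponential (KS test)", {
  p <- sim_params(alpha = 1.5, beta = 0, mode = "constant", duration = 60,
                  n_worms = 150, seed = 13)
  pop <- simulate_population(p, record_m = FALSE)
  gaps <- unlist(lapply(pop, function(tr) diff(tr$event_times)))
  expect_gt(length(gaps), 1e4)
  ks <- suppressWarnings(stats::ks.test(gaps, "pexp", rate = 1.5))
  expect_gt(ks$p.value, 0.01)
})

test_that("ensemble M(t) and Omega(t) match their closed forms", {
  p <- sim_params(n_worms = 600, seed = 21)
  pop <- simulate_population(p)
  checkpoints <- seq(4.5, 45, by = 4.5)

  m_at <- function(tr, t) {
    tr$m_path$M[findInterval(t, tr$m_path$time_min)]
  }
  for (t in checkpoints) {
    m <- vapply(pop, m_at, numeric(1), t = t)
    expect_lt(abs(mean(m) - p$m0 * exp(-p$gamma * t)),
              3 * sd(m) / sqrt(length(m)) + 1e-9)
  }
  for (t in checkpoints) {
    om <- vapply(pop, function(tr) sum(tr$event_times <= t), numeric(1))
    closed <- p$alpha / p$gamma * (1 - exp(-p$gamma * t)) + p$beta * t
    expect_lt(abs(mean(om) - closed), 3 * sd(om) / sqrt(length(om)))
  }
})

test_that("M0 = 1 is a two-state system with rates alpha+beta and beta", {
  p <- sim_params(m0 = 1, n_worms = 20, seed = 17)
  pop <- simulate_population(p)
  for (tr in pop) {
    expect_true(all(tr$m_path$M %in% c(0L, 1L)))
    rates <- vapply(tr$m_path$M,
                    function(m) compute_propensities(m, p)$a1, numeric(1))
    expect_true(all(rates %in% c(p$alpha + p$beta, p$beta)))
  }
})

test_that("population initialized from rates matches them at t = 0", {
  p <- sim_params(n_worms = 200, seed = 29)
  rates <- sample_initial_rates(initial_rate_model(), 200, seed = 30)
  pop <- simulate_population(p, initial_rates = rates)
  rc <- population_rate(pop)
  r0 <- rc$rate[rc$time_min == 0]
  se <- rc$sd[rc$time_min == 0] / sqrt(200)
  # clamp/rounding make the realised target mean(pmin(rates, alpha+beta))
  target <- mean(pmin(pmax(rates, p$beta), p$alpha + p$beta))
  expect_lt(abs(r0 - target), 3 * se)
})
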