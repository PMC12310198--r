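cps_df <- function(sd, tt) {
  data.frame(worm_id = seq_along(sd), slope_diff = sd, t_trans = tt)
}

test_that("binning normalises, clips, and respects quadrants", {
  ex <- c(0, 1, 2); ey <- c(0, 10, 20)
  one <- bin_distribution(cps_df(0.5, 5), ex, ey)
  expect_equal(sum(one$probs), 1)
  expect_equal(one$probs[1, 1], 1)

  quad <- bin_distribution(cps_df(c(0.5, 1.5, 0.5, 1.5),
                                  c(5, 5, 15, 15)), ex, ey)
  expect_true(all(quad$probs == 0.25))

  # out-of-range mass is clipped into the end bins, none lost
  clip <- bin_distribution(cps_df(c(-3, 9), c(-2, 99)), ex, ey)
  expect_equal(clip$probs[1, 1], 0.5)
  expect_equal(clip$probs[2, 2], 0.5)

  set.seed(6)
  big <- bin_distribution(cps_df(rnorm(1000), runif(1000, 0, 20)), ex, ey)
  expect_equal(sum(big$probs), 1)

  expect_error(bin_distribution(cps_df(numeric(0), numeric(0)), ex, ey),
               "empty")
})

test_that("KL divergence matches hand-computed values", {
  p <- as_binned(c(1, 0))
  q <- as_binned(c(0.5, 0.5))
  expect_equal(kl_divergence(p, p), 0)
  expect_equal(kl_divergence(p, q), log(2))
  expect_identical(kl_divergence(q, p), Inf)

  r <- as_binned(c(0.5, 0.25, 0.25))
  expect_error(kl_divergence(p, r), "edges")
})

test_that("JSD matches closed forms, is symmetric and bounded", {
  p <- as_binned(c(1, 0))
  q <- as_binned(c(0.5, 0.5))
  expect_equal(jsd(p, p), 0)
  # 0.5*ln(4/3) + 0.5*(0.5*ln(2/3) + 0.5*ln 2), frozen from independent
  # evaluation of the mixture construction
  expect_equal(jsd(p, q), 0.2157615543, tolerance = 1e-9)
  expect_equal(jsd(p, as_binned(c(0, 1))), log(2))

  set.seed(42)
  for (i in 1:50) {
    a <- matrix(rexp(12), 3); a <- a / sum(a)
    b <- matrix(rexp(12), 3); b <- b / sum(b)
    pa <- as_binned(a); pb <- as_binned(b)
    d <- jsd(pa, pb)
    expect_identical(d, jsd(pb, pa))
    expect_gte(d, 0)
    expect_lte(d, log(2) + 1e-12)
  }
})

test_that("JSD ignores bins empty in both distributions", {
  a <- c(0.6, 0.4); b <- c(0.2, 0.8)
  d0 <- jsd(as_binned(a), as_binned(b))
  d1 <- jsd(as_binned(c(a, 0, 0)), as_binned(c(b, 0, 0)))
  expect_equal(d0, d1)
})

test_that("marginal JSDs collapse the joint correctly", {
  ex <- seq(-1, 3, 1); ey <- seq(0, 40, 10)
  p <- bin_distribution(cps_df(c(0.5, 1.5, 2.5), c(5, 15, 25)), ex, ey)
  expect_equal(unname(jsd_marginals(p, p)), c(0, 0))
  q <- bin_distribution(cps_df(c(0.5, 0.5, 0.5), c(5, 15, 25)), ex, ey)
  m <- jsd_marginals(p, q)
  expect_gt(m["slope_diff"], 0)
  expect_equal(unname(m["t_trans"]), 0)
})

test_that("best_match maximises Pearson correlation on shared grids", {
  t <- seq(0, 10, 0.5)
  mk <- function(y) structure(data.frame(time_min = t, omega = y),
                              class = c("cumulative_curve", "data.frame"))
  ref <- mk(2 * t)
  cands <- list(mk(t^2), mk(2 * t + 1), mk(10 - t))
  bm <- best_match(ref, cands)
  expect_identical(bm$index, 2L)  # affine in the reference: correlation 1
  expect_equal(bm$correlation, 1)
  # hand-check the argmax ordering
  cors <- sapply(cands, function(c) cor(ref$omega, c$omega))
  expect_identical(bm$index, which.max(cors))

  expect_identical(best_match(ref, list(ref))$index, 1L)

  # zero-variance candidates are skipped with a message
  expect_message(
    bm2 <- best_match(ref, list(mk(rep(3, length(t))), mk(t))),
    "zero-variance")
  expect_identical(bm2$index, 2L)

  short <- data.frame(time_min = t[1:5], omega = t[1:5])
  expect_error(best_match(ref, list(short)), "grid")
})

test_that("self-comparison JSD sits at the split-half sampling floor", {
  pop <- simulate_population(sim_params(n_worms = 200, seed = 314),
                             record_m = FALSE)
  cps <- population_changepoints(pop)
  edges <- default_bin_edges(cps, bins = 10)
  halves <- list(cps[1:100, ], cps[101:200, ])
  b <- lapply(halves, bin_distribution, edges_x = edges$edges_x,
              edges_y = edges$edges_y)
  noise_floor <- jsd(b[[1]], b[[2]])
  # an independent population from the same generative process should be
  # about as close as the two halves are to each other
  pop2 <- simulate_population(sim_params(n_worms = 100, seed = 2718),
                              record_m = FALSE)
  d <- jsd(bin_distribution(population_changepoints(pop2),
                            edges$edges_x, edges$edges_y),
           bin_distribution(cps, edges$edges_x, edges$edges_y))
  expect_lt(d, 3 * noise_floor)
})
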