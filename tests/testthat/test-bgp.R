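linear_reps <- function(n_rep = 3, tg = seq(0.5, 25, by = 0.5), noise = 0,
                        slope = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_rep), function(r)
    data.frame(time_s = tg, count = slope * tg + rnorm(length(tg), 0, noise),
               replicate_id = r))
}

test_that("noiseless identical replicates are reproduced almost exactly", {
  reps <- linear_reps(noise = 0)
  fit <- fit_bgp(reps, bgp_config(transform = "identity"), seed = 1)
  truth <- 10 * fit$t_grid
  expect_lt(max(abs(fit$post_mean - truth) / truth), 0.01)
  interior <- fit$t_grid > 3 & fit$t_grid < 22
  expect_lt(max(fit$post_sd[interior] / truth[interior]), 0.01)
  expect_true(all(fit$post_sd >= 0))
  expect_true(all(is.finite(fit$post_mean)))
})

test_that("the fit is seed-deterministic and validates inputs", {
  reps <- linear_reps(noise = 2, seed = 30)
  cfg <- bgp_config(transform = "identity")
  f1 <- fit_bgp(reps, cfg, seed = 5)
  f2 <- fit_bgp(reps, cfg, seed = 5)
  expect_identical(f1$post_mean, f2$post_mean)
  expect_identical(f1$post_sd, f2$post_sd)
  expect_error(fit_bgp(list(), cfg, seed = 1), "empty input")
  expect_error(fit_bgp(reps, cfg), "seed")
})

test_that("a single replicate yields a wider posterior than three", {
  tg <- seq(0.5, 25, by = 0.5)
  kin <- kinetics_params(1e6, 1e-12, 1e-8, 200, duration = 30)
  f <- expected_counts(kin, c(0, tg))[-1]
  cfg <- bgp_config(transform = "identity")
  set.seed(31)
  mk <- function(r) data.frame(time_s = tg,
                               count = f + rnorm(length(tg), 0, 5),
                               replicate_id = r)
  r3 <- lapply(1:3, mk)
  f1 <- fit_bgp(r3[1], cfg, seed = 9)
  f3 <- fit_bgp(r3, cfg, seed = 9)
  expect_gt(mean(f1$post_sd), mean(f3$post_sd))
})

test_that("MCMC inference runs with sane diagnostics and is reproducible", {
  reps <- linear_reps(n_rep = 3, tg = seq(1, 20, by = 1), noise = 3,
                      seed = 32)
  cfg <- bgp_config(transform = "identity", inference = "mcmc",
                    draws = 300, warmup = 150, chains = 2, hyper_draws = 30)
  f1 <- fit_bgp(reps, cfg, seed = 4)
  f2 <- fit_bgp(reps, cfg, seed = 4)
  expect_identical(f1$post_mean, f2$post_mean)
  expect_true(all(is.finite(f1$diagnostics$rhat)))
  expect_lt(max(f1$diagnostics$rhat), 1.3)
  expect_gt(f1$diagnostics$accept_rate, 0.05)
  truth <- 10 * f1$t_grid
  expect_lt(max(abs(f1$post_mean - truth) / truth), 0.15)
})

test_that("endpoint estimates interpolate the posterior without extrapolating", {
  reps <- linear_reps(noise = 0)
  fit <- fit_bgp(reps, bgp_config(transform = "identity"), seed = 1)
  g <- fit$t_grid
  at_grid <- endpoint_estimate(fit, g[10])
  expect_equal(at_grid$estimate, fit$post_mean[10])
  expect_equal(at_grid$post_sd, fit$post_sd[10])
  mid <- (g[10] + g[11]) / 2
  expect_equal(endpoint_estimate(fit, mid)$estimate,
               (fit$post_mean[10] + fit$post_mean[11]) / 2, tolerance = 1e-12)
  # monotone posterior mean gives monotone endpoints
  e1 <- endpoint_estimate(fit, g[5])$estimate
  e2 <- endpoint_estimate(fit, g[40])$estimate
  expect_gte(e2, e1)
  expect_error(endpoint_estimate(fit, max(g) + 1), "outside")
})

test_that("the naive baseline is the plain replicate mean and sd", {
  tg <- c(5, 10)
  reps <- lapply(c(90, 100, 110), function(v)
    data.frame(time_s = tg, count = c(v / 2, v), replicate_id = v))
  nv <- naive_estimate(reps, 10)
  expect_equal(nv$estimate, 100)
  expect_equal(nv$sd, 10)
  same <- lapply(1:3, function(r) data.frame(time_s = tg, count = c(1, 7),
                                             replicate_id = r))
  expect_equal(naive_estimate(same, 10)$sd, 0)
  expect_error(naive_estimate(same[1], 10), ">= 2 replicates")
})

test_that("replicate endpoint sd approaches the digital noise limit sqrt(N)", {
  lambda <- 400
  set.seed(33)
  vals <- rpois(4000, lambda)
  # many-replicate naive sd converges to sqrt(lambda)
  reps <- lapply(seq_along(vals), function(i)
    data.frame(time_s = c(1, 2), count = c(0, vals[i]), replicate_id = i))
  nv <- naive_estimate(reps, 2)
  expect_lt(abs(nv$sd - sqrt(lambda)) / sqrt(lambda), 0.06)
  expect_lt(abs(nv$estimate - lambda), 3 * sqrt(lambda / length(vals)))
})

test_that("anscombe back-transform is consistent in the small-noise limit", {
  tg <- seq(1, 30, by = 1)
  counts <- 5 * tg
  reps <- lapply(1:3, function(r)
    data.frame(time_s = tg, count = counts, replicate_id = r))
  fit <- fit_bgp(reps, bgp_config(transform = "anscombe_sqrt"), seed = 2)
  expect_lt(max(abs(fit$post_mean - counts) / counts), 0.02)
})
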