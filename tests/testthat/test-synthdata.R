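test_that("expected_counts validates its time grid", {
  kin <- kinetics_params(1e6, 1e-12, 1e-8, 100, duration = 10)
  expect_error(expected_counts(kin, numeric(0)), "empty time grid")
  expect_error(expected_counts(kin, c(1, 2)), "start at 0")
  expect_error(expected_counts(kin, c(0, 2, 2)), "strictly increasing")
})

test_that("expected_counts: no analyte means no events", {
  kin <- kinetics_params(1e6, 0, 1e-8, 100, duration = 10)
  expect_identical(expected_counts(kin, c(0, 1, 5, 10)), rep(0, 4))
})

test_that("expected_counts is exactly linear without site depletion", {
  kin <- kinetics_params(k_on = 2, analyte_conc = 3, probe_conc = 4,
                         fov_site_count = Inf, k_off = 0, duration = 10)
  tg <- c(0, 0.5, 1, 5, 10)
  expect_equal(expected_counts(kin, tg), 2 * 3 * 4 * tg,
               tolerance = 1e-12)
})

test_that("expected_counts matches a Runge-Kutta oracle under depletion", {
  skip_if_not_installed("deSolve")
  # r = k_on * [P] = 0.01 per site per second, 100 sites, 300 s
  kin <- kinetics_params(1e6, 1e-12, 1e-8, 100, k_off = 0, duration = 300)
  tg <- seq(0, 300, by = 5)
  rk <- deSolve::ode(c(N = 0), tg,
                     function(t, y, p) list(0.01 * (100 - y[1])), NULL,
                     method = "rk4", hini = 0.01)
  expect_lt(max(abs(expected_counts(kin, tg) - rk[, "N"])), 0.1)

  # with rebinding (k_off > 0) counts keep growing past occupancy equilibrium
  kin2 <- kinetics_params(1e6, 1e-12, 1e-8, 100, k_off = 0.02, duration = 300)
  rk2 <- deSolve::ode(c(B = 0, N = 0), tg, function(t, y, p)
    list(c(0.01 * (100 - y[1]) - 0.02 * y[1], 0.01 * (100 - y[1]))), NULL)
  N2 <- expected_counts(kin2, tg)
  expect_lt(max(abs(N2 - rk2[, "N"])), 0.1)
  late_slope <- diff(tail(N2, 2)) / 5
  expect_gt(late_slope, 0.1)   # linear growth after equilibrium
})

test_that("expected_counts is non-decreasing in time and in each rate", {
  tg <- seq(0, 60, by = 2)
  base <- list(k_on = 1e6, analyte_conc = 1e-12, probe_conc = 1e-8,
               fov_site_count = 50, k_off = 0.01, duration = 60)
  N0 <- expected_counts(do.call(kinetics_params, base), tg)
  expect_true(all(diff(N0) >= 0))
  expect_identical(N0[1], 0)
  for (par in c("k_on", "probe_conc")) {
    up <- base; up[[par]] <- up[[par]] * 2
    N1 <- expected_counts(do.call(kinetics_params, up), tg)
    expect_true(all(N1 - N0 >= -1e-12), info = par)
  }
})

test_that("sample_events is reproducible and honors trivial cases", {
  opt <- optics_params()
  kin0 <- kinetics_params(1e6, 0, 1e-8, 100, duration = 10)
  expect_identical(nrow(sample_events(kin0, opt, seed = 1)), 0L)

  kin <- kinetics_params(1e6, 1e-12, 1e-8, 60, duration = 120)
  a <- sample_events(kin, opt, seed = 42)
  b <- sample_events(kin, opt, seed = 42)
  expect_identical(a, b)
  c_ <- sample_events(kin, opt, seed = 43)
  expect_false(identical(a, c_))
  expect_true(all(a$t_off_s > a$t_on_s))
  expect_error(sample_events(kin, opt), "seed")
})

test_that("sticky-site configuration is echoed in the ground truth", {
  opt <- optics_params()
  kin <- kinetics_params(1e6, 0, 1e-8, 0, duration = 60)
  ns <- nonspecific_config(sticky_sites = 5, sticky_visits = 3)
  ev <- sample_events(kin, opt, ns, seed = 7)
  stk <- ev[ev$label == "nonspecific_sticky", ]
  expect_identical(length(unique(stk$site_id)), 5L)
  expect_true(all(table(stk$site_id) >= 3))
  # all visits of one site share a location
  for (s in unique(stk$site_id)) {
    sub <- stk[stk$site_id == s, ]
    expect_lt(max(dist(cbind(sub$x_px, sub$y_px))), 1e-12)
  }
})

test_that("wrong-mass events fall outside the antibody mass window", {
  opt <- optics_params()
  kin <- kinetics_params(1e6, 0, 1e-8, 0, duration = 60)
  ns <- nonspecific_config(mass_events = 40,
                           mass_ranges = list(c(10, 50), c(300, 600)))
  ev <- sample_events(kin, opt, ns, seed = 8)
  expect_identical(nrow(ev), 40L)
  expect_true(all(ev$mass_kda < 60 | ev$mass_kda > 250))
})

test_that("sampled event counts are an unbiased Poisson draw of the kinetics", {
  opt <- optics_params()
  # low-occupancy constant-rate regime: per-site p = 0.0297
  kin <- kinetics_params(1e6, 1e-12, 1e-8, 200, duration = 3)
  expected <- tail(expected_counts(kin, c(0, 3)), 1)
  n <- vapply(1:600, function(s)
    nrow(sample_events(kin, opt, seed = 1000 + s)), numeric(1))
  se <- sd(n) / sqrt(length(n))
  expect_lt(abs(mean(n) - expected), 3 * se)
  expect_gt(var(n) / mean(n), 0.85)
  expect_lt(var(n) / mean(n), 1.1)
})

test_that("render_stack with no events and no noise is the bare background", {
  opt <- quiet_optics()
  ev <- sample_events(kinetics_params(1e6, 0, 1e-8, 0, duration = 1),
                     opt, seed = 1)
  rs <- render_stack(ev, opt, c(4, 24, 24), seed = 1)
  for (f in 1:4)
    expect_equal(get_frame(rs$stack, f), matrix(100, 24, 24))
})

test_that("render_stack draws the exact Gaussian forward model", {
  opt <- quiet_optics(frame_interval = 1)
  ev <- data.frame(event_id = 1L, site_id = 1L, x_px = 11.3, y_px = 12.6,
                   t_on_s = 0.05, t_off_s = 10, mass_kda = 150,
                   label = "specific")
  rs <- render_stack(ev, opt, c(3, 24, 24), seed = 1)
  A <- 0.47 * 150
  expected <- 100 + gauss_image(24, 24, 11.3, 12.6, A, opt$psf_sigma)
  # exact within the rendering window (+/- 4 sigma); tails truncate below
  # 3e-4 of the amplitude
  got <- get_frame(rs$stack, 2)
  expect_equal(got[8:18, 7:17], expected[8:18, 7:17], tolerance = 1e-12)
  expect_lt(max(abs(got - expected)), 3.4e-4 * A)
  # linear in amplitude: doubling the mass response doubles the spot
  opt2 <- quiet_optics(frame_interval = 1, intensity_per_kda = 0.94)
  rs2 <- render_stack(ev, opt2, c(3, 24, 24), seed = 1)
  expect_equal(get_frame(rs2$stack, 2) - 100,
               2 * (get_frame(rs$stack, 2) - 100), tolerance = 1e-12)
})

test_that("render_stack is seed-deterministic and validates coordinates", {
  opt <- optics_params()
  ev <- data.frame(event_id = 5L, site_id = 1L, x_px = 40, y_px = 10,
                   t_on_s = 0.2, t_off_s = 2, mass_kda = 150,
                   label = "specific")
  a <- render_stack(ev, opt, c(5, 32, 64), seed = 3)
  b <- render_stack(ev, opt, c(5, 32, 64), seed = 3)
  expect_identical(a$stack$pixels, b$stack$pixels)
  expect_true(all(a$stack$pixels >= 0))
  expect_error(render_stack(ev, opt, c(5, 32, 32), seed = 3), "5")
  expect_error(render_stack(ev, opt, c(1, 64, 64), seed = 3), ">= 2")
})
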