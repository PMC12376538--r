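test_that("mass calibration recovers an exact line with zero SEs", {
  pts <- data.frame(mass_kda = c(50, 150, 400, 900),
                    mean_intensity = 2 * c(50, 150, 400, 900) + 5)
  cal <- fit_mass_calibration(pts)
  expect_equal(cal$slope, 2, tolerance = 1e-12)
  expect_equal(cal$intercept, 5, tolerance = 1e-10)
  expect_equal(cal$slope_se, 0)
  expect_equal(cal$intercept_se, 0)
  expect_error(fit_mass_calibration(pts[1, ]), "at least 2")
  pts$mass_kda <- 100
  expect_error(fit_mass_calibration(pts), "degenerate calibration")
})

test_that("weighted calibration is unbiased under heteroscedastic noise", {
  masses <- c(66, 150, 385, 970)
  ses <- c(1, 2, 5, 12)
  set.seed(20)
  slopes <- replicate(400, {
    pts <- data.frame(mass_kda = masses,
                      mean_intensity = 0.5 * masses + 3 + rnorm(4, 0, ses),
                      intensity_se = ses)
    fit_mass_calibration(pts)$slope
  })
  se_mean <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 0.5), 3 * se_mean)
})

test_that("mass_of inverts the calibration line with propagated error", {
  cal <- fit_mass_calibration(
    data.frame(mass_kda = c(50, 150, 400), mean_intensity = 2 * c(50, 150, 400) + 5))
  expect_equal(mass_of(cal, 5)$mass_kda, 0)
  expect_equal(mass_of(cal, 305)$mass_kda, 150)
  m <- runif(20, 10, 900)
  expect_equal(mass_of(cal, 2 * m + 5)$mass_kda, m, tolerance = 1e-9)
})

test_that("classification labels each event once with a reason code", {
  cal <- make_cal()
  cfg <- event_filter_config(mass_window_kda = c(60, 250),
                             min_duration_s = 1, max_duration_s = 100,
                             colocation_radius_px = 1.5, max_site_visits = 1)
  tr <- data.frame(event_id = 1:6,
                   x_px = c(10, 10.2, 10.1, 40, 60, 80),
                   y_px = c(10, 10.1, 9.9, 40, 60, 80),
                   t_on_s = c(1, 5, 9, 2, 3, 4),
                   t_off_s = c(3, 7, 11, 150, 13, 4.5),
                   refined_intensity = 0.47 * c(150, 150, 150, 150, 500, 150))
  out <- classify_events(tr, cal, cfg)
  expect_identical(out$reason[1:3], rep("repeated_site", 3))
  expect_identical(out$reason[4], "too_long")
  expect_identical(out$reason[5], "mass_out_of_window")
  expect_identical(out$reason[6], "too_short")
  expect_true(all(out$label %in% c("specific", "nonspecific")))
  # exactly one label per event, partition preserved
  expect_identical(sum(out$label == "specific") +
                     sum(out$label == "nonspecific"), nrow(out))
  expect_error(classify_events(tr, NULL, cfg), "missing calibration")

  # a clean single event is specific
  one <- classify_events(tr[4, ][, -5] |>
                           transform(t_off_s = 50), cal, cfg)
  expect_identical(one$label, "specific")
})

test_that("widening filters never decreases the specific count", {
  cal <- make_cal()
  set.seed(21)
  n <- 80
  tr <- data.frame(event_id = 1:n,
                   x_px = runif(n, 0, 60), y_px = runif(n, 0, 60),
                   t_on_s = runif(n, 0, 50), t_off_s = 60,
                   refined_intensity = 0.47 * runif(n, 30, 400))
  base <- event_filter_config(mass_window_kda = c(100, 200),
                              colocation_radius_px = 2, max_site_visits = 1)
  n0 <- sum(classify_events(tr, cal, base)$label == "specific")
  wide <- event_filter_config(mass_window_kda = c(50, 400),
                              colocation_radius_px = 2, max_site_visits = 1)
  expect_gte(sum(classify_events(tr, cal, wide)$label == "specific"), n0)
  lax <- event_filter_config(mass_window_kda = c(100, 200),
                             colocation_radius_px = 2, max_site_visits = 5)
  expect_gte(sum(classify_events(tr, cal, lax)$label == "specific"), n0)
})

test_that("count series accumulate arrivals and never decrement", {
  ev <- data.frame(t_on_s = c(1, 2, 2, 7), label = "specific")
  cs <- build_count_series(ev, c(0, 5, 10))
  expect_equal(cs$count, c(0, 3, 4))
  expect_equal(build_count_series(ev[0, ], c(0, 5, 10))$count, rep(0, 3))
  # conservation at the final grid point
  expect_equal(tail(cs$count, 1), nrow(ev))
  expect_error(build_count_series(ev, c(5, 5, 10)), "strictly increasing")
})
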