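test_that("block averaging matches a naive loop oracle", {
  set.seed(10)
  px <- array(rnorm(20 * 12 * 12, 100, 5), dim = c(20, 12, 12))
  st <- frame_stack(px, 0.01)
  avg <- rolling_average(st, 5)
  expect_identical(n_frames(avg), 4L)
  expect_equal(avg$frame_interval, 0.05)
  expect_equal(avg$pixels, naive_block_average(px, 5), tolerance = 1e-12)
  # identity and constant cases
  expect_equal(rolling_average(st, 1)$pixels, px)
  cs <- const_stack()
  expect_equal(rolling_average(cs, 5)$pixels[1, , ], cs$pixels[1, , ])
  expect_error(rolling_average(st, 21), "longer than")
})

test_that("normalization removes multiplicative drift and keeps scale", {
  base <- matrix(runif(16 * 16, 80, 120), 16, 16)
  px <- array(0, dim = c(8, 16, 16))
  for (k in 1:8) px[k, , ] <- base * (1 + 0.01 * k)
  st <- frame_stack(px, 0.1)
  out <- normalize_frames(st)
  fmeans <- apply(out$pixels, 1, mean)
  expect_lt(diff(range(fmeans)), 1e-10)
  # all frames collapse to the same image, global scale preserved
  for (k in 2:8)
    expect_equal(out$pixels[k, , ], out$pixels[1, , ], tolerance = 1e-12)
  expect_equal(mean(out$pixels), mean(px), tolerance = 1e-12)
  # uniform-mean stack is unchanged
  st2 <- const_stack()
  expect_equal(normalize_frames(st2)$pixels, st2$pixels)
  bad <- frame_stack(array(0, dim = c(2, 4, 4)), 0.1)
  expect_error(normalize_frames(bad), "degenerate frame")
})

test_that("a static spot keeps its contrast under source modulation", {
  base <- matrix(100, 32, 32)
  spot <- gauss_image(32, 32, 15.2, 16.7, 40, 1.5)
  px <- array(0, dim = c(12, 32, 32))
  for (k in 1:12) px[k, , ] <- (base + spot) * (1 + 0.05 * sin(k))
  out <- normalize_frames(frame_stack(px, 0.1))
  contrast <- apply(out$pixels, 1, function(m) max(m) - median(m))
  expect_lt(diff(range(contrast)) / mean(contrast), 1e-10)
})

test_that("differencing removes statics and signs arrivals/departures", {
  cs <- const_stack()
  expect_true(all(differential(cs)$pixels == 0))
  expect_error(differential(const_stack(F = 1)), "at least 2")

  base <- matrix(100, 24, 24)
  spot <- gauss_image(24, 24, 10, 12, 50, 1.5)
  px <- array(0, dim = c(10, 24, 24))
  for (k in 1:10) px[k, , ] <- base + if (k >= 6 && k < 9) spot else 0
  dif <- differential(frame_stack(px, 0.1))
  expect_identical(n_frames(dif), 9L)
  # appears at frame 6 (1-based): positive blob only in differential frame 5
  expect_equal(dif$pixels[5, , ], spot, tolerance = 1e-12)
  expect_equal(max(abs(dif$pixels[6, , ])), 0)
  # disappears at frame 9: negative blob in differential frame 8
  expect_equal(dif$pixels[8, , ], -spot, tolerance = 1e-12)
})

test_that("adding a constant to every raw pixel changes nothing downstream", {
  set.seed(11)
  px <- array(rnorm(12 * 20 * 20, 100, 4), dim = c(12, 20, 20))
  p1 <- differential(normalize_frames(rolling_average(frame_stack(px, 0.1), 3)))
  # scale equivariance: c * stack scales every differential frame by c
  p2 <- differential(normalize_frames(rolling_average(
    frame_stack(3 * px, 0.1), 3)))
  expect_equal(p2$pixels, 3 * p1$pixels, tolerance = 1e-10)
})

test_that("probability image equals the naive correlation oracle", {
  k <- haar_kernel(1.5)
  expect_equal(sum(k), 0, tolerance = 1e-15)
  set.seed(12)
  img <- matrix(rnorm(64 * 64, 0, 3), 64, 64) +
    gauss_image(64, 64, 30.4, 33.8, 25, 1.5)
  pim <- probability_image(img, k)
  oracle <- naive_correlation(img, k)
  expect_equal(pim$values, oracle, tolerance = 1e-9)
  # constant frame maps to exactly zero (zero-sum kernel)
  pc <- probability_image(matrix(7, 32, 32), k)
  expect_lt(max(abs(pc$values), na.rm = TRUE), 1e-10)
  expect_error(probability_image(matrix(0, 5, 5), k), "larger than frame")
})

test_that("3-sigma exceedance on pure noise matches the normal tail", {
  k <- haar_kernel(1.5)
  r <- (nrow(k) - 1) %/% 2
  set.seed(13)
  hits <- 0; tot <- 0
  for (rep in 1:30) {
    pim <- probability_image(matrix(rnorm(96 * 96), 96, 96), k)
    v <- pim$values
    mu <- mean(v, na.rm = TRUE); sdv <- sd(v[is.finite(v)])
    # sample kernel-spaced pixels so counts are effectively independent
    idx_r <- seq(r + 1, 96 - r, by = 2 * r + 1)
    sub <- v[idx_r, idx_r]
    hits <- hits + sum(sub > mu + 3 * sdv)
    tot <- tot + length(sub)
  }
  p <- pnorm(3, lower.tail = FALSE)
  se <- sqrt(p * (1 - p) / tot)
  expect_lt(abs(hits / tot - p), 3 * se + 1e-6)
})

test_that("candidate selection thresholds, suppresses and errors correctly", {
  k <- haar_kernel(1.5)
  expect_error(find_candidates(probability_image(matrix(5, 32, 32), k)),
               "flat probability image")
  set.seed(14)
  img <- matrix(rnorm(64 * 64, 0, 2), 64, 64)
  img <- img + gauss_image(64, 64, 31, 31, 60, 1.5)
  cands <- find_candidates(probability_image(img, k))
  expect_identical(nrow(cands), 1L)
  expect_equal(unname(c(cands$row, cands$col)), c(32, 32), tolerance = 0)

  # two blobs 3 kernel radii apart -> two candidates; 0.5 radii -> one
  rad <- (nrow(k) - 1) / 2
  img2 <- matrix(rnorm(64 * 64, 0, 2), 64, 64) +
    gauss_image(64, 64, 20, 30, 60, 1.5) +
    gauss_image(64, 64, 20 + 3 * rad, 30, 60, 1.5)
  expect_identical(nrow(find_candidates(probability_image(img2, k))), 2L)
  img3 <- matrix(rnorm(64 * 64, 0, 2), 64, 64) +
    gauss_image(64, 64, 30, 30, 60, 1.5) +
    gauss_image(64, 64, 30 + 0.5 * rad, 30, 60, 1.5)
  expect_identical(nrow(find_candidates(probability_image(img3, k))), 1L)
})

test_that("spot fitting recovers a noiseless blob to sub-pixel precision", {
  img <- gauss_image(41, 41, 20.3, 19.8, 100, 1.5) + 5
  ft <- fit_spot(img, list(row = 21, col = 21), roi_halfwidth = 5,
                 psf_sigma = 1.5)
  expect_true(ft$accepted)
  expect_equal(ft$x, 20.3, tolerance = 1e-6)
  expect_equal(ft$y, 19.8, tolerance = 1e-6)
  expect_equal(ft$amplitude, 100, tolerance = 1e-4)
  expect_equal(ft$sigma, 1.5, tolerance = 1e-6)
  expect_equal(ft$offset, 5, tolerance = 1e-4)
})

test_that("out-of-band morphology and structureless noise are rejected", {
  # blob much wider than the nominal PSF trips the sigma gate
  img <- gauss_image(41, 41, 20, 20, 100, 4) +
    matrix(rnorm(41 * 41, 0, 0.5), 41, 41)
  ft <- fit_spot(img, list(row = 21, col = 21), roi_halfwidth = 8,
                 psf_sigma = 1.5)
  expect_false(ft$accepted)
  expect_identical(ft$reason, "sigma_out_of_band")

  # pure-noise regions: mostly rejected per-frame, and never significant
  # under the trace-level skip-difference amplitude test
  set.seed(15)
  acc <- logical(40); tstat <- numeric(40)
  for (i in 1:40) {
    nz <- matrix(rnorm(41 * 41, 0, 10), 41, 41)
    ft <- fit_spot(nz, list(row = 21, col = 21), roi_halfwidth = 5,
                   psf_sigma = 1.5)
    acc[i] <- isTRUE(ft$accepted)
    m <- lfsmia:::measure_amplitude(nz, 20, 20, 1.5, 5)
    tstat[i] <- m$t
  }
  expect_lt(mean(acc), 0.5)
  expect_true(all(tstat < 7, na.rm = TRUE))
})

test_that("trace linking merges by distance and gap and takes the peak", {
  fits <- data.frame(frame = 0:3, x = 10.1, y = 10.05,
                     amplitude = c(3, 9, 7, 2), sigma = 1.5,
                     residual_norm = 0.1)
  tr <- assemble_traces(fits, linking_radius = 2, gap_frames = 1)
  expect_identical(nrow(tr), 1L)
  expect_equal(tr$peak_intensity, 9)
  expect_equal(tr$onset_intensity, 16)   # largest adjacent-frame sum (9 + 7)
  expect_identical(c(tr$t_on_frame, tr$t_off_frame), c(0L, 3L))

  two <- rbind(fits, transform(fits, x = 20.1))
  expect_identical(nrow(assemble_traces(two, 2, 1)), 2L)

  # 1-frame dropout: merged with gap_frames = 2, split with gap_frames = 0
  gap <- data.frame(frame = c(0, 1, 3), x = 5, y = 5,
                    amplitude = c(4, 8, 5), sigma = 1.5, residual_norm = 0.1)
  expect_identical(nrow(assemble_traces(gap, 2, 2)), 1L)
  expect_identical(nrow(assemble_traces(gap, 2, 0)), 2L)
  expect_identical(nrow(assemble_traces(gap[0, ], 2, 1)), 0L)
})
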