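# shared fixtures and independent naive oracles

# exact calibration table on intensity = 0.47 * MW (four reference proteins)
make_cal_table <- function(noise_sd = 0) {
  masses <- c(66, 150, 385, 970)
  set.seed(99)
  data.frame(species = c("BSA", "IgG", "IgA", "IgM"), mass_kda = masses,
             mean_intensity = 0.47 * masses + rnorm(4, 0, noise_sd),
             intensity_se = c(1, 1, 2, 4))
}

make_cal <- function(...) fit_mass_calibration(make_cal_table(...))

# a constant-background FrameStack
const_stack <- function(F = 10, nr = 16, nc = 16, value = 100, dt = 0.1) {
  frame_stack(array(value, dim = c(F, nr, nc)), dt)
}

# direct evaluation of the rendered Gaussian at pixel centers (0-based)
gauss_image <- function(nr, nc, x, y, A, sigma) {
  gy <- exp(-((seq_len(nr) - 1 - y)^2) / (2 * sigma^2))
  gx <- exp(-((seq_len(nc) - 1 - x)^2) / (2 * sigma^2))
  A * outer(gy, gx)
}

# naive O(F) block average oracle
naive_block_average <- function(px, n) {
  F <- dim(px)[1]; nb <- F %/% n
  out <- array(0, dim = c(nb, dim(px)[2], dim(px)[3]))
  for (b in seq_len(nb)) {
    acc <- 0
    for (j in ((b - 1) * n + 1):(b * n)) acc <- acc + px[j, , ]
    out[b, , ] <- acc / n
  }
  out
}

# naive O(N^2 K^2) cross-correlation oracle (valid region only, NA border)
naive_correlation <- function(img, kernel) {
  r <- (nrow(kernel) - 1) %/% 2
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(NA_real_, nr, nc)
  for (i in (r + 1):(nr - r)) {
    for (j in (r + 1):(nc - r)) {
      acc <- 0
      for (a in -r:r) for (b in -r:r)
        acc <- acc + img[i + a, j + b] * kernel[a + r + 1, b + r + 1]
      out[i, j] <- acc
    }
  }
  out
}

# quiet optics for deterministic rendering
quiet_optics <- function(...) {
  optics_params(background_level = 100, speckle_fraction = 0,
                read_noise_sd = 0, shot_noise = FALSE, ...)
}
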