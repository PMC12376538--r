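#' Configuration of the Bayesian Gaussian-process count model
#'
#' The model treats the replicate cumulative count series of one condition
#' as noisy observations of a single latent trajectory f(t): on a
#' variance-stabilized scale (the Anscombe square root, appropriate for
#' Poisson-like counts, or the identity), each replicate's transformed
#' counts are f(t) plus independent Gaussian replicate noise, and f has a
#' Gaussian-process prior with a squared-exponential kernel around a mean
#' function fit to the pooled data. Hyperparameters (kernel amplitude,
#' length-scale, noise sd) carry log-normal / half-normal hyperpriors whose
#' locations default to data-driven scales at fit time.
#'
#' @param kernel covariance kernel; only \code{"squared_exponential"}.
#' @param mean_function \code{"linear_in_time"} (weighted straight line fit
#'   to the pooled transformed counts, the GP models the residual) or
#'   \code{"zero_on_transformed"}.
#' @param noise_scale scale of the half-normal hyperprior on the replicate
#'   noise sd; \code{NULL} uses the pooled residual sd.
#' @param amp_prior,ls_prior optional c(meanlog, sdlog) of the log-normal
#'   hyperpriors on kernel amplitude and length-scale; \code{NULL} centers
#'   them on the residual sd and a quarter of the time span.
#' @param transform \code{"anscombe_sqrt"} (2 * sqrt(N + 3/8)) or
#'   \code{"identity"}.
#' @param inference \code{"map_plus_laplace"} (fast: marginal-likelihood MAP
#'   with hyperparameter uncertainty propagated through a Laplace
#'   approximation) or \code{"mcmc"} (random-walk Metropolis on the
#'   hyperparameters).
#' @param draws,warmup,chains MCMC settings (per chain).
#' @param hyper_draws hyperparameter draws mixed into the posterior of f.
#' @param grid_max maximum number of fitting grid points; the union of
#'   replicate time grids is thinned evenly beyond this.
#' @param monotone_projection apply an isotonic (non-decreasing) projection
#'   to the posterior mean after back-transform; off by default because the
#'   GP prior itself does not enforce monotonicity.
#' @return A \code{BGPConfig} object.
#' @export
bgp_config <- function(kernel = "squared_exponential",
                       mean_function = c("linear_in_time", "zero_on_transformed"),
                       noise_scale = NULL, amp_prior = NULL, ls_prior = NULL,
                       transform = c("anscombe_sqrt", "identity"),
                       inference = c("map_plus_laplace", "mcmc"),
                       draws = 1000L, warmup = 500L, chains = 2L,
                       hyper_draws = 40L, grid_max = 200L,
                       monotone_projection = FALSE) {
  kernel <- match.arg(kernel)
  mean_function <- match.arg(mean_function)
  transform <- match.arg(transform)
  inference <- match.arg(inference)
  stopifnot(draws >= 1, chains >= 1, hyper_draws >= 1, grid_max >= 10)
  structure(list(kernel = kernel, mean_function = mean_function,
                 noise_scale = noise_scale, amp_prior = amp_prior,
                 ls_prior = ls_prior, transform = transform,
                 inference = inference, draws = as.integer(draws),
                 warmup = as.integer(warmup), chains = as.integer(chains),
                 hyper_draws = as.integer(hyper_draws),
                 grid_max = as.integer(grid_max),
                 monotone_projection = isTRUE(monotone_projection)),
            class = "BGPConfig")
}

anscombe <- function(n) 2 * sqrt(n + 3 / 8)

## moments of N = (Y/2)^2 - 3/8 for Y ~ N(m, v) (exact for the square)
inv_anscombe_moments <- function(m, v) {
  mean_n <- (m^2 + v) / 4 - 3 / 8
  var_n <- (m^2 * v + v^2 / 2) / 4
  list(mean = mean_n, sd = sqrt(pmax(var_n, 0)))
}

se_kernel <- function(t1, t2, amp, ls) {
  d <- outer(t1, t2, "-")
  amp^2 * exp(-0.5 * (d / ls)^2)
}

## prior covariance of f: SE kernel plus, when the mean function is a fitted
## line, a weakly-informative linear basis-function term that carries the
## line's own uncertainty into the posterior band
make_kernel <- function(basis) {
  function(t1, t2, amp, ls) {
    K <- se_kernel(t1, t2, amp, ls)
    if (!is.null(basis))
      K <- K + basis$v0 + basis$v1 * outer(t1 - basis$t0, t2 - basis$t0)
    K
  }
}

## negative log joint (marginal likelihood + hyperpriors) at
## theta = (log amp, log ls, log sigma); r = pooled residuals at times tt
bgp_nlp <- function(theta, tt, r, priors, kern = se_kernel) {
  amp <- exp(theta[1]); ls <- exp(theta[2]); sg <- exp(theta[3])
  n <- length(r)
  K <- kern(tt, tt, amp, ls)
  diag(K) <- diag(K) + sg^2 + 1e-8 * (max(diag(K)) + sg^2) + 1e-12
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  alpha <- backsolve(ch, forwardsolve(t(ch), r))
  nll <- 0.5 * sum(r * alpha) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)
  lp <- stats::dnorm(theta[1], priors$amp[1], priors$amp[2], log = TRUE) +
    stats::dnorm(theta[2], priors$ls[1], priors$ls[2], log = TRUE) +
    (-sg^2 / (2 * priors$noise^2) + theta[3])   # half-normal + log jacobian
  nll - lp
}

## GP posterior of (mean function + f) on `grid` for one hyperparameter set
bgp_conditional <- function(theta, tt, r, grid, mean_grid,
                            kern = se_kernel) {
  amp <- exp(theta[1]); ls <- exp(theta[2]); sg <- exp(theta[3])
  K <- kern(tt, tt, amp, ls)
  diag(K) <- diag(K) + sg^2 + 1e-8 * (max(diag(K)) + sg^2) + 1e-12
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Ks <- kern(grid, tt, amp, ls)
  alpha <- backsolve(ch, forwardsolve(t(ch), r))
  mu <- mean_grid + drop(Ks %*% alpha)
  V <- forwardsolve(t(ch), t(Ks))
  prior_diag <- diag(kern(grid, grid, amp, ls))
  var_f <- pmax(prior_diag - colSums(V^2), 0)
  list(mean = mu, var = var_f)
}

#' Fit the Bayesian Gaussian-process model to replicate count series
#'
#' Pools the replicates of one condition, transforms the counts, fits the
#' mean function, and infers the latent shared trajectory f(t) under a
#' squared-exponential GP prior with replicate-level Gaussian noise.
#' Hyperparameters are inferred by MAP with a Laplace approximation (or by
#' Metropolis MCMC), and the posterior of f mixes over hyperparameter draws.
#' Results are back-transformed to count units.
#'
#' @param replicates list of \code{CountSeries} (or a single data.frame with
#'   a \code{replicate_id} column); all replicates of one condition.
#' @param cfg a \code{BGPConfig}.
#' @param seed integer seed; mandatory, same seed gives identical output.
#' @return A \code{BGPFit}: list with \code{t_grid}, \code{post_mean},
#'   \code{post_sd} (posterior mean and sd of the latent count trajectory),
#'   \code{post_mean_trans}, \code{post_sd_trans} (transformed scale),
#'   \code{hyper_summary}, \code{diagnostics}, \code{transform},
#'   \code{n_replicates}.
#' @export
fit_bgp <- function(replicates, cfg = bgp_config(), seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(inherits(cfg, "BGPConfig"))
  if (is.data.frame(replicates))
    replicates <- split(replicates, replicates$replicate_id)
  if (length(replicates) == 0L) stop("empty input: no replicates")
  obs <- do.call(rbind, lapply(replicates, function(r)
    data.frame(time_s = r$time_s, count = r$count)))
  if (any(!is.finite(obs$count)))
    stop("counts must be finite")
  if (cfg$transform == "anscombe_sqrt" && any(obs$count < -3 / 8))
    stop("counts below -3/8 are incompatible with the Anscombe transform")

  y <- switch(cfg$transform,
              anscombe_sqrt = anscombe(obs$count),
              identity = obs$count)
  tt <- obs$time_s

  ## fitting grid: union of replicate grids, thinned evenly
  grid <- sort(unique(tt))
  if (length(grid) > cfg$grid_max)
    grid <- grid[unique(round(seq(1, length(grid), length.out = cfg$grid_max)))]

  ## mean function on the transformed scale
  if (cfg$mean_function == "linear_in_time") {
    mf <- stats::lm(y ~ tt)
    mean_obs <- stats::fitted(mf)
    mean_grid <- stats::predict(mf, newdata = data.frame(tt = grid))
    ## weakly-informative linear basis kernel so the posterior band carries
    ## the fitted line's own uncertainty
    sy <- max(stats::sd(y - mean_obs), 1e-3)
    st <- max(stats::sd(tt), 1e-9)
    basis <- list(v0 = (3 * sy)^2, v1 = (3 * sy / st)^2, t0 = mean(tt))
  } else {
    mean_obs <- rep(0, length(y))
    mean_grid <- rep(0, length(grid))
    basis <- NULL
  }
  kern <- make_kernel(basis)
  r <- y - mean_obs

  span <- max(tt) - min(tt)
  if (span <= 0) span <- 1
  s_r <- max(stats::sd(r), 1e-3)
  priors <- list(
    amp = if (is.null(cfg$amp_prior)) c(log(s_r), 1.5) else cfg$amp_prior,
    ls = if (is.null(cfg$ls_prior)) c(log(span / 4), 1) else cfg$ls_prior,
    noise = if (is.null(cfg$noise_scale)) s_r else cfg$noise_scale)

  withr::with_seed(as.integer(seed), {
    theta0 <- c(priors$amp[1], priors$ls[1], log(s_r / 2))
    opt <- stats::optim(theta0, bgp_nlp, tt = tt, r = r, priors = priors,
                        kern = kern,
                        method = "Nelder-Mead",
                        control = list(maxit = 500))
    opt <- stats::optim(opt$par, bgp_nlp, tt = tt, r = r, priors = priors,
                        kern = kern,
                        method = "BFGS", hessian = TRUE,
                        control = list(maxit = 200))
    if (!all(is.finite(opt$par))) stop("hyperparameter optimization diverged")
    H <- opt$hessian
    Sig <- tryCatch(solve(H + diag(1e-8, 3)), error = function(e) NULL)
    if (is.null(Sig) || any(diag(Sig) <= 0))
      Sig <- diag(1e-4, 3)
    Sig <- (Sig + t(Sig)) / 2
    ee <- eigen(Sig, symmetric = TRUE)
    ev <- pmax(ee$values, 1e-10)
    L <- ee$vectors %*% diag(sqrt(ev))

    diagnostics <- list(method = cfg$inference,
                        convergence = opt$convergence,
                        nlp = opt$value)

    if (cfg$inference == "map_plus_laplace") {
      nd <- cfg$hyper_draws
      thetas <- matrix(opt$par, nd, 3, byrow = TRUE) +
        matrix(stats::rnorm(nd * 3), nd, 3) %*% t(L)
      thetas[1, ] <- opt$par   # always include the MAP itself
    } else {
      ## random-walk Metropolis, Laplace covariance as proposal scale
      prop_L <- L * (2.4 / sqrt(3))
      nkeep <- cfg$draws
      all_draws <- vector("list", cfg$chains)
      acc_tot <- 0L
      cur_nlp <- NULL
      for (ch in seq_len(cfg$chains)) {
        th <- opt$par + drop(prop_L %*% stats::rnorm(3))
        cur <- bgp_nlp(th, tt, r, priors, kern)
        keep <- matrix(NA_real_, nkeep, 3)
        for (it in seq_len(cfg$warmup + nkeep)) {
          prop <- th + drop(prop_L %*% stats::rnorm(3))
          new <- bgp_nlp(prop, tt, r, priors, kern)
          if (stats::runif(1) < exp(cur - new)) {
            th <- prop; cur <- new
            if (it > cfg$warmup) acc_tot <- acc_tot + 1L
          }
          if (it > cfg$warmup) keep[it - cfg$warmup, ] <- th
        }
        all_draws[[ch]] <- keep
      }
      draws_mat <- do.call(rbind, all_draws)
      diagnostics$accept_rate <- acc_tot / (cfg$chains * nkeep)
      diagnostics$rhat <- split_rhat(all_draws)
      diagnostics$ess <- apply(draws_mat, 2, crude_ess)
      idx <- round(seq(1, nrow(draws_mat),
                       length.out = min(cfg$hyper_draws, nrow(draws_mat))))
      thetas <- draws_mat[idx, , drop = FALSE]
    }

    ## mix GP conditionals over hyperparameter draws; draws whose kernel is
    ## numerically singular are skipped (the MAP draw always succeeds first)
    mix_mean <- 0; mix_m2 <- 0; nmix <- 0L
    for (i in seq_len(nrow(thetas))) {
      cn <- bgp_conditional(thetas[i, ], tt, r, grid, mean_grid, kern)
      if (is.null(cn)) next
      mix_mean <- mix_mean + cn$mean
      mix_m2 <- mix_m2 + cn$var + cn$mean^2
      nmix <- nmix + 1L
    }
    if (nmix == 0L) stop("posterior conditioning failed for all draws")
    post_mean_t <- mix_mean / nmix
    post_var_t <- pmax(mix_m2 / nmix - post_mean_t^2, 0)
    post_sd_t <- sqrt(post_var_t)

    if (cfg$transform == "anscombe_sqrt") {
      bt <- inv_anscombe_moments(post_mean_t, post_var_t)
      post_mean <- bt$mean; post_sd <- bt$sd
    } else {
      post_mean <- post_mean_t; post_sd <- post_sd_t
    }
    if (cfg$monotone_projection)
      post_mean <- stats::isoreg(grid, post_mean)$yf

    hs <- data.frame(
      parameter = c("amplitude", "length_scale", "noise_sd"),
      map = exp(opt$par),
      post_mean = exp(colMeans(thetas)),
      post_sd = apply(exp(thetas), 2, stats::sd))

    post_mean <- unname(post_mean); post_sd <- unname(post_sd)
    post_mean_t <- unname(post_mean_t); post_sd_t <- unname(post_sd_t)
    structure(list(t_grid = grid, post_mean = post_mean, post_sd = post_sd,
                   post_mean_trans = post_mean_t, post_sd_trans = post_sd_t,
                   hyper_summary = hs, diagnostics = diagnostics,
                   transform = cfg$transform,
                   monotone_projection = cfg$monotone_projection,
                   n_replicates = length(replicates)),
              class = "BGPFit")
  })
}

split_rhat <- function(chain_list) {
  ## split-chain potential scale reduction, per parameter
  halves <- list()
  for (ch in chain_list) {
    n <- nrow(ch); h <- n %/% 2L
    halves <- c(halves, list(ch[seq_len(h), , drop = FALSE],
                             ch[(h + 1L):(2L * h), , drop = FALSE]))
  }
  vapply(1:3, function(p) {
    m <- length(halves); n <- nrow(halves[[1]])
    means <- vapply(halves, function(x) mean(x[, p]), numeric(1))
    vars <- vapply(halves, function(x) stats::var(x[, p]), numeric(1))
    W <- mean(vars); B <- n * stats::var(means)
    if (W <= 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}

crude_ess <- function(x) {
  n <- length(x)
  ac <- stats::acf(x, lag.max = min(100L, n - 1L), plot = FALSE)$acf[-1]
  pos <- which(ac < 0.05)
  cut <- if (length(pos)) pos[1] - 1L else length(ac)
  n / (1 + 2 * sum(ac[seq_len(cut)]))
}

#' @export
print.BGPFit <- function(x, ...) {
  cat(sprintf(
    "BGPFit: %d replicates, %d grid points, transform = %s\n  endpoint %.1f +/- %.2f counts\n",
    x$n_replicates, length(x$t_grid), x$transform,
    x$post_mean[length(x$post_mean)], x$post_sd[length(x$post_sd)]))
  invisible(x)
}

#' Model-based endpoint estimate
#'
#' Linear interpolation of the posterior mean and sd of the latent count
#' trajectory at time T. No extrapolation: T must lie inside the fitted
#' grid.
#'
#' @param fit a \code{BGPFit}.
#' @param T time in seconds.
#' @return list with \code{estimate} and \code{post_sd}.
#' @export
endpoint_estimate <- function(fit, T) {
  stopifnot(inherits(fit, "BGPFit"))
  if (T < min(fit$t_grid) || T > max(fit$t_grid))
    stop("T outside the fitted grid (no extrapolation)")
  list(estimate = stats::approx(fit$t_grid, fit$post_mean, xout = T)$y,
       post_sd = stats::approx(fit$t_grid, fit$post_sd, xout = T)$y)
}

#' Model-free endpoint baseline
#'
#' The plain replicate mean and sample sd of the counts at time T (step
#' interpolation of each replicate's cumulative series). This is the
#' no-model baseline the GP's precision gain is measured against.
#'
#' @param replicates list of \code{CountSeries} (or data.frame with
#'   \code{replicate_id}).
#' @param T time in seconds.
#' @return list with \code{estimate} (mean), \code{sd} (sample sd) and
#'   \code{values} (per-replicate endpoint counts).
#' @export
naive_estimate <- function(replicates, T) {
  if (is.data.frame(replicates))
    replicates <- split(replicates, replicates$replicate_id)
  if (length(replicates) < 2L)
    stop("need >= 2 replicates for a sample sd")
  vals <- vapply(replicates, function(r) {
    if (T < min(r$time_s) - 1e-9) return(0)
    stats::approx(r$time_s, r$count, xout = min(T, max(r$time_s)),
                  method = "constant", rule = 2)$y
  }, numeric(1))
  list(estimate = mean(vals), sd = stats::sd(vals), values = unname(vals))
}
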