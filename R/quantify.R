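#' Fit a standard curve
#'
#' Fits endpoint count estimates against analyte concentration, weighted by
#' 1/sd^2. Two models are available: \code{loglog_linear},
#' log10(count) = a * log10(conc) + b (the default, matching the straight
#' lines these assays show on log-log axes), and \code{four_pl}, the
#' 4-parameter logistic in log10 concentration for saturating ranges. Both
#' expose forward and inverse evaluation; the inverse is monotone on the
#' fitted range.
#'
#' @param points data.frame with columns \code{concentration} (> 0, any
#'   consistent unit), \code{estimate} (> 0 counts) and optionally
#'   \code{sd}.
#' @param model \code{"loglog_linear"} or \code{"four_pl"}.
#' @param baseline background count level (e.g. the blank-condition
#'   estimate) subtracted before a log-log fit and added back by
#'   \code{forward}; points whose net signal is not positive are dropped
#'   with a warning. Ignored by \code{four_pl}, whose bottom asymptote
#'   plays that role.
#' @return A \code{StandardCurve} with elements \code{model},
#'   \code{coefficients}, \code{forward} (conc -> count), \code{inverse}
#'   (count -> conc), \code{baseline}, \code{points}, \code{warnings}.
#' @export
fit_standard_curve <- function(points, model = c("loglog_linear", "four_pl"),
                               baseline = 0) {
  model <- match.arg(model)
  stopifnot(is.data.frame(points),
            all(c("concentration", "estimate") %in% names(points)))
  if (any(points$concentration <= 0)) stop("concentrations must be > 0")
  if (any(points$estimate <= 0)) stop("estimates must be > 0")
  warns <- character(0)
  if (model == "loglog_linear" && baseline > 0) {
    net <- points$estimate - baseline
    drop_ <- net <= 0
    if (any(drop_)) {
      warns <- c(warns, sprintf("%d point(s) at or below the baseline dropped",
                                sum(drop_)))
      points <- points[!drop_, , drop = FALSE]
    }
  }
  if (model == "four_pl" && nrow(points) < 4L)
    stop("four_pl needs >= 4 points")
  if (nrow(points) < 3L) stop("need >= 3 non-blank concentrations")
  o <- order(points$concentration)
  if (any(diff(points$estimate[o]) <= 0))
    warns <- c(warns, "non-monotone estimates over concentration")
  sd_ok <- "sd" %in% names(points) && all(is.finite(points$sd)) &&
    all(points$sd > 0)

  if (model == "loglog_linear") {
    net <- points$estimate - baseline
    lx <- log10(points$concentration); ly <- log10(net)
    # sd on log10(net count) via delta method
    w <- if (sd_ok) (net * log(10) / points$sd)^2
         else rep(1, nrow(points))
    fit <- stats::lm(ly ~ lx, weights = w)
    cf <- stats::coef(fit)
    a <- unname(cf[2]); b <- unname(cf[1])
    if (a <= 0) warns <- c(warns, "non-positive log-log slope")
    vc <- suppressWarnings(stats::vcov(fit))
    coefs <- c(slope = a, intercept = b)
    forward <- function(conc) baseline + 10^(a * log10(conc) + b)
    inverse <- function(count) {
      if (any(count <= baseline))
        stop("count at or below the baseline cannot be inverted")
      10^((log10(count - baseline) - b) / a)
    }
    cov_mat <- vc
  } else {
    if (nrow(points) < 4L) stop("four_pl needs >= 4 points")
    lx <- log10(points$concentration)
    y <- points$estimate
    w <- if (sd_ok) 1 / points$sd^2 else rep(1, nrow(points))
    d0 <- min(y) * 0.9; a0 <- max(y) * 1.1
    c0 <- stats::median(lx); b0 <- 1
    df <- data.frame(y = y, lx = lx)
    fit <- minpack.lm::nlsLM(
      y ~ d + (a - d) / (1 + 10^(b * (c - lx))),
      data = df, weights = w,
      start = list(a = a0, b = b0, c = c0, d = d0),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(fit)
    a <- cf[["a"]]; b <- cf[["b"]]; cc <- cf[["c"]]; d <- cf[["d"]]
    coefs <- c(top = a, slope = b, log10_ec50 = cc, bottom = d)
    forward <- function(conc)
      d + (a - d) / (1 + 10^(b * (cc - log10(conc))))
    inverse <- function(count) {
      if (any(count <= d) || any(count >= a))
        stop("count outside the 4PL response range")
      10^(cc - log10((a - d) / (count - d) - 1) / b)
    }
    cov_mat <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  }
  if (length(warns)) for (w_ in warns) warning(w_, call. = FALSE)
  structure(list(model = model, coefficients = coefs, cov = cov_mat,
                 forward = forward, inverse = inverse, baseline = baseline,
                 points = points, warnings = warns),
            class = "StandardCurve")
}

#' @export
print.StandardCurve <- function(x, ...) {
  cat(sprintf("StandardCurve [%s]: %s\n", x$model,
              paste(sprintf("%s = %.4g", names(x$coefficients),
                            x$coefficients), collapse = ", ")))
  invisible(x)
}

#' Limit of detection from the blank signal
#'
#' The LOD threshold is the blank posterior mean plus three times the blank
#' posterior sd; the LOD concentration is that count threshold mapped
#' through the inverse standard curve.
#'
#' @param blank list or vector with \code{mean} and \code{post_sd} of the
#'   blank-condition signal (counts).
#' @param curve a \code{StandardCurve}.
#' @param n_sigma multiplier on the blank sd (default 3).
#' @return An \code{LODResult}: \code{blank_mean}, \code{blank_post_sd},
#'   \code{threshold_count}, \code{lod_concentration}.
#' @export
compute_lod <- function(blank, curve, n_sigma = 3) {
  stopifnot(inherits(curve, "StandardCurve"))
  blank <- as.list(blank)
  if (is.null(names(blank)) || !all(c("mean", "post_sd") %in% names(blank))) {
    if (length(blank) == 2L) names(blank) <- c("mean", "post_sd")
    else stop("blank must supply mean and post_sd")
  }
  thr <- blank$mean + n_sigma * blank$post_sd
  if (!is.finite(thr) || thr <= 0)
    stop("blank threshold must be positive to invert the curve")
  conc <- tryCatch(curve$inverse(thr), error = function(e)
    stop("threshold not invertible on the fitted curve: ",
         conditionMessage(e)))
  structure(list(blank_mean = blank$mean, blank_post_sd = blank$post_sd,
                 threshold_count = thr, lod_concentration = conc),
            class = "LODResult")
}

#' Coefficient of variation
#' @param estimate point estimate (> 0).
#' @param sd its standard deviation.
#' @return sd / estimate.
#' @export
cv <- function(estimate, sd) {
  if (any(estimate <= 0)) stop("estimate must be > 0")
  sd / estimate
}

#' CV improvement ratio
#'
#' The factor by which the model reduces the coefficient of variation
#' relative to the replicate-sd baseline: naive_cv / model_cv.
#'
#' @param model_cv CV from the GP posterior sd.
#' @param naive_cv CV from the sample sd of replicates.
#' @return improvement ratio (> 1 means the model is more precise).
#' @export
cv_improvement <- function(model_cv, naive_cv) {
  if (any(model_cv <= 0)) stop("model_cv must be > 0")
  naive_cv / model_cv
}

#' Detectable dynamic range in decades
#'
#' @param curve a \code{StandardCurve} (context; not evaluated).
#' @param lod an \code{LODResult} or the LOD concentration itself.
#' @param upper_limit highest quantifiable concentration, same units.
#' @return log10(upper_limit / LOD concentration).
#' @export
dynamic_range <- function(curve = NULL, lod, upper_limit) {
  lo <- if (inherits(lod, "LODResult")) lod$lod_concentration else lod
  if (!is.finite(lo) || lo <= 0) stop("LOD concentration must be > 0")
  if (upper_limit <= lo) stop("upper limit must exceed the LOD")
  log10(upper_limit / lo)
}

#' Pearson correlation and regression slope of paired measurements
#'
#' Used to compare assay-measured concentrations against a reference method:
#' returns the sample Pearson r and the ordinary least-squares slope of y on
#' x.
#'
#' @param x,y paired numeric vectors (>= 3 finite pairs).
#' @return list with \code{r} and \code{slope}.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need >= 3 finite pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  list(r = stats::cor(x, y),
       slope = unname(stats::coef(stats::lm(y ~ x))[2]))
}
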