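#' Fit the intensity-to-molecular-weight calibration line
#'
#' Spot intensity in plasmonic scattering images is linear in the molecular
#' weight of the bound particle. The calibration is a weighted least-squares
#' line \code{intensity = slope * mass + intercept}, with weights
#' 1/intensity_se^2 when per-point standard errors are given (unit weights
#' otherwise), fit to per-species mean intensities.
#'
#' @param points data.frame with columns \code{mass_kda},
#'   \code{mean_intensity}, and optionally \code{intensity_se} and
#'   \code{species}.
#' @return A \code{MassCalibration}: slope, intercept, their standard
#'   errors, the parameter covariance and the calibration table.
#' @export
fit_mass_calibration <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("mass_kda", "mean_intensity") %in% names(points)))
  if (nrow(points) < 2L) stop("need at least 2 calibration points")
  if (length(unique(points$mass_kda)) < 2L) stop("degenerate calibration")
  w <- if ("intensity_se" %in% names(points) &&
           all(is.finite(points$intensity_se)) &&
           all(points$intensity_se > 0)) 1 / points$intensity_se^2
       else rep(1, nrow(points))
  fit <- stats::lm(mean_intensity ~ mass_kda, data = points, weights = w)
  cf <- stats::coef(fit)
  sm <- suppressWarnings(summary(fit))
  se <- sm$coefficients[, "Std. Error"]
  vc <- suppressWarnings(stats::vcov(fit))
  # a perfect 2-point (or exact) fit has zero residual df / zero residuals
  if (!all(is.finite(se)) || sm$sigma < 1e-12 || is.nan(sm$sigma)) {
    se <- c(0, 0); vc <- matrix(0, 2, 2)
  }
  if (cf[["mass_kda"]] <= 0) stop("calibration slope must be positive")
  structure(list(slope = unname(cf[["mass_kda"]]),
                 intercept = unname(cf[["(Intercept)"]]),
                 slope_se = unname(se[2]), intercept_se = unname(se[1]),
                 cov = unname(vc), points = points),
            class = "MassCalibration")
}

#' @export
print.MassCalibration <- function(x, ...) {
  cat(sprintf(
    "MassCalibration: intensity = %.4g * MW + %.4g (se %.3g, %.3g), %d points\n",
    x$slope, x$intercept, x$slope_se, x$intercept_se, nrow(x$points)))
  invisible(x)
}

#' Convert spot intensity to molecular weight
#'
#' Inverts the calibration line: mass = (intensity - intercept) / slope,
#' with first-order uncertainty propagated from the slope/intercept
#' covariance.
#'
#' @param cal a \code{MassCalibration}.
#' @param intensity numeric vector of spot intensities (counts).
#' @return data.frame with \code{mass_kda} and \code{mass_se}.
#' @export
mass_of <- function(cal, intensity) {
  stopifnot(inherits(cal, "MassCalibration"))
  m <- (intensity - cal$intercept) / cal$slope
  # gradient wrt (intercept, slope): (-1/a, -m/a)
  va <- cal$cov[2, 2]; vb <- cal$cov[1, 1]; cab <- cal$cov[1, 2]
  se <- sqrt(pmax((vb + m^2 * va + 2 * m * cab) / cal$slope^2, 0))
  data.frame(mass_kda = m, mass_se = se)
}

#' Event-filter configuration
#'
#' Gates implementing the position / molecular weight / duration / frequency
#' filtering of detected binding events. An event is specific only if its
#' estimated mass lies inside \code{mass_window_kda}, its dwell inside the
#' duration gates, and its co-location cluster holds at most
#' \code{max_site_visits} events over the whole record (binding at the same
#' location multiple times marks a nonspecific sticky site).
#'
#' @param mass_window_kda (low, high) accepted molecular weight in kDa.
#' @param min_duration_s,max_duration_s dwell gates in seconds.
#' @param colocation_radius_px radius defining "the same location".
#' @param max_site_visits events allowed per site before the whole site is
#'   flagged nonspecific; >= 1.
#' @return An \code{EventFilterConfig} object.
#' @export
event_filter_config <- function(mass_window_kda = c(60, 250),
                                min_duration_s = 0, max_duration_s = Inf,
                                colocation_radius_px = 1.5,
                                max_site_visits = 1L) {
  stopifnot(length(mass_window_kda) == 2L,
            mass_window_kda[1] < mass_window_kda[2],
            min_duration_s >= 0, max_duration_s > min_duration_s,
            colocation_radius_px > 0, max_site_visits >= 1)
  structure(list(mass_window_kda = mass_window_kda,
                 min_duration_s = min_duration_s,
                 max_duration_s = max_duration_s,
                 colocation_radius_px = colocation_radius_px,
                 max_site_visits = as.integer(max_site_visits)),
            class = "EventFilterConfig")
}

#' Default mass window for a target binder
#'
#' Centers the accepted mass window on the binder's molecular weight with a
#' half-width of \code{n_sigma} times the propagated mass uncertainty at the
#' predicted intensity plus the measurement scatter expressed in mass units,
#' mirroring the 3-sigma style used elsewhere in the pipeline.
#'
#' @param cal a \code{MassCalibration}.
#' @param mass_kda target molecular weight.
#' @param intensity_sd expected sd of a measured spot intensity (counts).
#' @param n_sigma half-width multiplier (default 3).
#' @return numeric (low, high) window in kDa.
#' @export
default_mass_window <- function(cal, mass_kda = 150, intensity_sd = 0,
                                n_sigma = 3) {
  pred <- cal$slope * mass_kda + cal$intercept
  cal_se <- mass_of(cal, pred)$mass_se
  meas_se <- intensity_sd / cal$slope
  half <- n_sigma * sqrt(cal_se^2 + meas_se^2)
  c(mass_kda - half, mass_kda + half)
}

## single-linkage co-location clusters; returns integer cluster id per event
colocation_clusters <- function(x, y, radius) {
  n <- length(x)
  if (n == 1L) return(1L)
  hc <- stats::hclust(stats::dist(cbind(x, y)), method = "single")
  stats::cutree(hc, h = radius)
}

#' Classify binding events as specific or nonspecific
#'
#' Labels every trace with exactly one of: \code{repeated_site} (its
#' co-location cluster has more than \code{max_site_visits} members over the
#' whole record), \code{mass_out_of_window}, \code{too_short},
#' \code{too_long}, or \code{specific}. Site clustering is single-linkage
#' with radius \code{colocation_radius_px}. The repeated-site rule is
#' applied first: a sticky site is nonspecific regardless of its mass.
#'
#' @param traces trace table from \code{\link{detect_events}} (needs
#'   \code{x_px}, \code{y_px}, \code{t_on_s}, \code{t_off_s} and an
#'   intensity column).
#' @param cal a \code{MassCalibration}.
#' @param cfg an \code{EventFilterConfig}.
#' @param intensity_col column used for mass estimation; defaults to the
#'   first available of \code{refined_intensity} (skip-difference
#'   re-measurement, free of block-phase attenuation),
#'   \code{onset_intensity}, \code{peak_intensity}.
#' @return \code{traces} with added columns \code{mass_kda},
#'   \code{mass_se}, \code{site_cluster}, \code{label}
#'   (specific/nonspecific) and \code{reason}.
#' @export
classify_events <- function(traces, cal, cfg = event_filter_config(),
                            intensity_col = NULL) {
  if (is.null(cal) || !inherits(cal, "MassCalibration"))
    stop("missing calibration")
  stopifnot(inherits(cfg, "EventFilterConfig"))
  if (nrow(traces) == 0L) {
    traces$mass_kda <- numeric(0); traces$mass_se <- numeric(0)
    traces$site_cluster <- integer(0)
    traces$label <- character(0); traces$reason <- character(0)
    return(traces)
  }
  if (is.null(intensity_col)) {
    pref <- c("refined_intensity", "onset_intensity", "peak_intensity")
    intensity_col <- pref[pref %in% names(traces)][1]
    if (is.na(intensity_col)) stop("no intensity column in traces")
  }
  mm <- mass_of(cal, traces[[intensity_col]])
  traces$mass_kda <- mm$mass_kda
  traces$mass_se <- mm$mass_se
  traces$site_cluster <- colocation_clusters(traces$x_px, traces$y_px,
                                             cfg$colocation_radius_px)
  sizes <- table(traces$site_cluster)
  repeated <- sizes[as.character(traces$site_cluster)] > cfg$max_site_visits
  dur <- traces$t_off_s - traces$t_on_s
  reason <- rep("specific", nrow(traces))
  reason[dur > cfg$max_duration_s] <- "too_long"
  reason[dur < cfg$min_duration_s] <- "too_short"
  reason[traces$mass_kda < cfg$mass_window_kda[1] |
           traces$mass_kda > cfg$mass_window_kda[2]] <- "mass_out_of_window"
  reason[repeated] <- "repeated_site"
  traces$reason <- reason
  traces$label <- ifelse(reason == "specific", "specific", "nonspecific")
  traces
}

#' Cumulative specific-binding count series
#'
#' Counts, at each grid time, the specific events that have arrived so far.
#' The series is cumulative: unbinding never decrements it, since the assay
#' signal is the number of binding events, not current occupancy.
#'
#' @param events classified event table (or any table with \code{t_on_s});
#'   only rows with \code{label == "specific"} are counted when a label
#'   column is present.
#' @param t_grid strictly increasing times in seconds.
#' @param replicate_id,condition labels attached to the series.
#' @return A \code{CountSeries}: data.frame with \code{time_s},
#'   \code{count}, \code{replicate_id}, \code{condition}.
#' @export
build_count_series <- function(events, t_grid, replicate_id = 1L,
                               condition = "") {
  if (length(t_grid) == 0L || (length(t_grid) > 1L && any(diff(t_grid) <= 0)))
    stop("t_grid must be non-empty and strictly increasing")
  t_on <- if ("label" %in% names(events))
    events$t_on_s[events$label == "specific"] else events$t_on_s
  counts <- vapply(t_grid, function(t) sum(t_on <= t), numeric(1))
  out <- data.frame(time_s = t_grid, count = counts,
                    replicate_id = replicate_id, condition = condition)
  class(out) <- c("CountSeries", "data.frame")
  out
}
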