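## merge user settings over defaults (shallow)
merge_cfg <- function(defaults, user) {
  if (is.null(user)) return(defaults)
  for (nm in names(user)) defaults[[nm]] <- user[[nm]]
  defaults
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

resolve_calibration <- function(calibration) {
  if (inherits(calibration, "MassCalibration")) return(calibration)
  if (is.character(calibration)) {
    if (grepl("\\.json$", calibration)) return(read_calibration(calibration))
    return(fit_mass_calibration(utils::read.csv(calibration)))
  }
  if (is.data.frame(calibration)) return(fit_mass_calibration(calibration))
  if (is.list(calibration))
    return(fit_mass_calibration(as.data.frame(calibration)))
  stop("calibration must be a MassCalibration, a table, or a file path")
}

#' Run the full assay pipeline
#'
#' Executes simulate (optional) -> detect -> classify -> BGP fit per
#' condition -> quantify, from a single nested configuration (built in R or
#' loaded from YAML with \code{\link{read_run_config}}). Each condition is
#' measured in replicates; per replicate a synthetic stack is generated from
#' the kinetics forward model (or a stack file is read), binding-event
#' traces are detected and classified, and cumulative specific-count series
#' are built. The replicate series of each condition are pooled by the
#' Bayesian GP model; endpoint estimates of the non-blank conditions form
#' the standard curve and the blank posterior gives the LOD.
#'
#' Configuration sections (all optional except \code{seed},
#' \code{conditions}, \code{calibration}):
#' \describe{
#'   \item{seed}{integer; governs every stochastic stage.}
#'   \item{conditions}{data.frame (or list of lists) with \code{label},
#'     \code{concentration} (0 = blank), \code{replicates}.}
#'   \item{calibration}{\code{MassCalibration}, calibration table
#'     (data.frame/CSV path) or calibration JSON path.}
#'   \item{synthdata}{\code{fov_px}, \code{frames}, \code{sites_per_unit}
#'     (field-of-view analyte sites per concentration unit),
#'     \code{antibody_mass_kda}, \code{optics} (args of
#'     \code{\link{optics_params}}), \code{kinetics} (\code{k_on},
#'     \code{probe_conc}, \code{k_off}), \code{nonspecific} (args of
#'     \code{\link{nonspecific_config}}), or \code{stacks} (per
#'     condition/replicate TIFF paths to skip simulation).}
#'   \item{detect}{args of \code{\link{detect_params}}.}
#'   \item{classify}{args of \code{\link{event_filter_config}};
#'     \code{min_duration_s} defaults to two averaged frame intervals.}
#'   \item{bgp}{args of \code{\link{bgp_config}}.}
#'   \item{quantify}{\code{curve_model}, \code{n_grid} (count-series grid
#'     points), \code{upper_limit} (for the dynamic range; defaults to the
#'     highest condition concentration).}
#'   \item{io}{\code{out_dir} to write trace/event/series CSVs, BGP and
#'     quantify JSONs and a manifest naming the config hash.}
#' }
#'
#' @param config nested list as described above.
#' @return list with \code{events} (all classified traces), \code{series},
#'   \code{fits} (per condition), \code{endpoints} (data.frame),
#'   \code{curve}, \code{lod}, \code{dynamic_range_decades},
#'   \code{manifest}.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$seed)) stop("validation: config must set a seed")
  if (is.null(config$conditions)) stop("validation: config must set conditions")
  if (is.null(config$calibration))
    stop("validation: config must supply a calibration")
  seed <- as.integer(config$seed)
  cal <- with_stage("calibration", resolve_calibration(config$calibration))

  conds <- config$conditions
  if (!is.data.frame(conds))
    conds <- do.call(rbind, lapply(conds, as.data.frame))
  stopifnot(all(c("label", "concentration", "replicates") %in% names(conds)))

  sdc <- merge_cfg(list(fov_px = c(128L, 128L), frames = 240L,
                        sites_per_unit = 1, antibody_mass_kda = 150,
                        optics = list(), kinetics = list(),
                        nonspecific = list(), stacks = NULL),
                   config$synthdata)
  opt <- do.call(optics_params, sdc$optics)
  kin_base <- merge_cfg(list(k_on = 1e6, probe_conc = 1e-8, k_off = 0),
                        sdc$kinetics)
  nonspec <- do.call(nonspecific_config, sdc$nonspecific)
  dp <- do.call(detect_params, merge_cfg(list(), config$detect))
  avg_dt <- dp$avg_window * opt$frame_interval
  duration <- sdc$frames * opt$frame_interval

  cls_args <- merge_cfg(list(min_duration_s = 2 * avg_dt), config$classify)
  fcfg <- do.call(event_filter_config, cls_args)
  bgp_cfg <- do.call(bgp_config, merge_cfg(list(), config$bgp))
  qt <- merge_cfg(list(curve_model = "loglog_linear", n_grid = 50L,
                       upper_limit = NULL), config$quantify)

  n_diff <- sdc$frames %/% dp$avg_window - 1L
  record_end <- (n_diff + 1) * avg_dt
  t_grid <- seq(2 * avg_dt, record_end, length.out = qt$n_grid)

  all_series <- list(); all_events <- list()
  for (ci in seq_len(nrow(conds))) {
    for (rp in seq_len(conds$replicates[ci])) {
      seed_cr <- seed + 7919L * ci + 101L * rp
      stack <- if (!is.null(sdc$stacks)) {
        with_stage("read", read_stack(sdc$stacks[[ci]][[rp]],
                                      opt$frame_interval, opt$pixel_size))
      } else {
        with_stage("simulate", {
          kin <- kinetics_params(
            k_on = kin_base$k_on,
            analyte_conc = conds$concentration[ci],
            probe_conc = kin_base$probe_conc,
            fov_site_count = round(conds$concentration[ci] *
                                     sdc$sites_per_unit),
            k_off = kin_base$k_off, duration = duration)
          ev <- sample_events(kin, opt, nonspec, seed_cr, sdc$fov_px,
                              sdc$antibody_mass_kda)
          render_stack(ev, opt, c(sdc$frames, sdc$fov_px), seed_cr + 1L)$stack
        })
      }
      det <- with_stage("detect", detect_events(stack, dp))
      evt <- with_stage("classify", classify_events(det$traces, cal, fcfg))
      ser <- with_stage("count", build_count_series(
        evt, t_grid, replicate_id = rp, condition = conds$label[ci]))
      if (nrow(evt)) {
        evt$condition <- conds$label[ci]; evt$replicate_id <- rp
      }
      all_events[[length(all_events) + 1L]] <- evt
      all_series[[paste(conds$label[ci], rp, sep = "/")]] <- ser
    }
  }

  ## BGP per condition
  fits <- list(); endpoints <- list()
  T_end <- max(t_grid)
  for (ci in seq_len(nrow(conds))) {
    lbl <- conds$label[ci]
    reps <- all_series[grep(paste0("^", lbl, "/"), names(all_series))]
    fit <- with_stage("bgp", fit_bgp(reps, bgp_cfg, seed = seed + 13L * ci))
    fits[[lbl]] <- fit
    ep <- endpoint_estimate(fit, T_end)
    nv <- if (length(reps) >= 2L) naive_estimate(reps, T_end)
          else list(estimate = NA_real_, sd = NA_real_)
    endpoints[[ci]] <- data.frame(
      label = lbl, concentration = conds$concentration[ci],
      estimate = ep$estimate, post_sd = ep$post_sd,
      naive_mean = nv$estimate, naive_sd = nv$sd)
  }
  endpoints <- do.call(rbind, endpoints)

  ## quantify
  nb <- endpoints[endpoints$concentration > 0, , drop = FALSE]
  bl <- endpoints[endpoints$concentration == 0, , drop = FALSE]
  baseline <- if (nrow(bl)) max(bl$estimate[1], 0) else 0
  curve <- NULL; lod <- NULL; dr <- NA_real_
  # points not significantly above the background level are below the
  # quantification floor and are excluded from the curve fit
  net <- nb$estimate - baseline
  quant <- net > 3 * nb$post_sd & net > 0
  nbq <- nb[quant, , drop = FALSE]
  if (nrow(nbq) >= 3L) {
    # too few quantifiable points is a data condition, not a failure:
    # report endpoints without a curve
    curve <- tryCatch(suppressWarnings(fit_standard_curve(
      data.frame(concentration = nbq$concentration,
                 estimate = nbq$estimate,
                 sd = pmax(nbq$post_sd, 1e-9)),
      model = qt$curve_model, baseline = baseline)),
      error = function(e) {
        message("standard curve not fitted: ", conditionMessage(e))
        NULL
      })
    if (nrow(bl)) {
      lod <- tryCatch(
        compute_lod(list(mean = max(bl$estimate[1], 0),
                         post_sd = bl$post_sd[1]), curve),
        error = function(e) { message("LOD not computed: ",
                                      conditionMessage(e)); NULL })
      if (!is.null(lod)) {
        upper <- if (is.null(qt$upper_limit)) max(nb$concentration)
                 else qt$upper_limit
        dr <- tryCatch(dynamic_range(curve, lod, upper),
                       error = function(e) NA_real_)
      }
    }
  }

  events <- do.call(rbind, all_events)
  series <- do.call(rbind, all_series)
  rownames(series) <- NULL
  manifest <- list(config_hash = config_hash(config), seed = seed,
                   package = "lfsmia",
                   version = as.character(utils::packageVersion("lfsmia")))

  out <- list(events = events, series = series, fits = fits,
              endpoints = endpoints, curve = curve, lod = lod,
              dynamic_range_decades = dr, manifest = manifest)

  if (!is.null(config$io$out_dir)) {
    dir.create(config$io$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$io$out_dir
    write_events_csv(events, file.path(od, "events.csv"))
    write_count_series(series, file.path(od, "count_series.csv"))
    for (lbl in names(fits))
      write_bgp_fit(fits[[lbl]], file.path(od, paste0("bgp_", lbl, ".json")))
    qres <- list(
      manifest = manifest,
      endpoints = endpoints,
      curve = if (!is.null(curve)) list(model = curve$model,
                                        coefficients = as.list(curve$coefficients)),
      lod = if (!is.null(lod)) unclass(lod),
      dynamic_range_decades = dr)
    jsonlite::write_json(qres, file.path(od, "quantify.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Match detected traces to ground-truth events
#'
#' Pairs each ground-truth event with the nearest unmatched detected trace
#' within \code{radius} pixels whose arrival time agrees within
#' \code{time_tol} seconds. Events arriving before the first differential
#' frame or after the last are outside the detector's temporal support and
#' are excluded from the denominator when \code{detectable_only} is TRUE
#' (frame differencing cannot, by construction, see an arrival that
#' precedes the first frame pair).
#'
#' @param traces detected trace table (\code{x_px}, \code{y_px},
#'   \code{t_on_s}).
#' @param truth ground-truth table from \code{\link{sample_events}}.
#' @param radius match radius in pixels.
#' @param time_tol arrival-time tolerance in seconds.
#' @param t_min,t_max detectable arrival window in seconds.
#' @param detectable_only restrict the denominator to the detectable window.
#' @return list with \code{recall}, \code{n_truth}, \code{n_matched},
#'   \code{rmse_px} (per-axis localization RMSE over matches) and
#'   \code{matches} (data.frame truth_id, trace_id, dx, dy, dt).
#' @export
match_traces <- function(traces, truth, radius = 2, time_tol,
                         t_min = -Inf, t_max = Inf, detectable_only = TRUE) {
  if (detectable_only)
    truth <- truth[truth$t_on_s >= t_min & truth$t_on_s <= t_max, ,
                   drop = FALSE]
  n_truth <- nrow(truth)
  used <- logical(nrow(traces))
  rows <- list()
  for (i in seq_len(n_truth)) {
    if (nrow(traces) == 0L) break
    d2 <- (traces$x_px - truth$x_px[i])^2 + (traces$y_px - truth$y_px[i])^2
    dt <- abs(traces$t_on_s - truth$t_on_s[i])
    ok <- !used & d2 <= radius^2 & dt <= time_tol
    if (any(ok)) {
      j <- which(ok)[which.min(d2[ok])]
      used[j] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        truth_id = truth$event_id[i], trace_id = traces$event_id[j],
        dx = traces$x_px[j] - truth$x_px[i],
        dy = traces$y_px[j] - truth$y_px[i],
        dt = traces$t_on_s[j] - truth$t_on_s[i])
    }
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(truth_id = integer(0), trace_id = integer(0),
               dx = numeric(0), dy = numeric(0), dt = numeric(0))
  rmse <- if (nrow(matches)) sqrt(mean(c(matches$dx^2, matches$dy^2)))
          else NA_real_
  list(recall = if (n_truth > 0) nrow(matches) / n_truth else NA_real_,
       n_truth = n_truth, n_matched = nrow(matches), rmse_px = rmse,
       matches = matches)
}
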