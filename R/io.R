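#' Read a multi-page grayscale TIFF into a FrameStack
#'
#' Pages are read in file order (frame order = time order). RGB or
#' multi-sample TIFFs are rejected; all pages must share one shape. Pixel
#' values are returned as floats in their stored integer units.
#'
#' @param path TIFF file.
#' @param frame_interval seconds per frame (config metadata; takes
#'   precedence over anything in the file).
#' @param pixel_size nm per pixel.
#' @return a raw \code{FrameStack}.
#' @export
read_stack <- function(path, frame_interval, pixel_size = NA_real_) {
  if (!file.exists(path)) stop("stack file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages) {
    if (length(dim(p)) == 3L)
      stop("RGB/multi-sample TIFF not supported: expected grayscale, got ",
           dim(p)[3], " channels")
  }
  shp <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), shp), logical(1))))
    stop("inconsistent page shapes in ", path)
  px <- array(0, dim = c(length(pages), shp[1], shp[2]))
  for (i in seq_along(pages)) px[i, , ] <- as.numeric(pages[[i]])
  frame_stack(px, frame_interval, pixel_size, "raw")
}

#' Write a FrameStack as a 16-bit multi-page grayscale TIFF
#'
#' Pixel values are rounded and clamped to [0, 65535]; frame order is time
#' order. Reading the file back with \code{\link{read_stack}} reproduces the
#' rounded pixels exactly.
#'
#' @param stack a \code{FrameStack}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "FrameStack"))
  F <- n_frames(stack)
  pages <- lapply(seq_len(F), function(i) {
    m <- round(get_frame(stack, i))
    m[m < 0] <- 0; m[m > 65535] <- 65535
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Write / read an event or trace table as CSV
#' @param events data.frame.
#' @param path CSV file.
#' @return \code{path} (write) or the data.frame (read).
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  if (!file.exists(path)) stop("event table not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read replicate count series as CSV
#'
#' Long format: \code{time_s}, \code{count}, \code{replicate_id},
#' \code{condition}.
#'
#' @param series a \code{CountSeries} or a row-bound set of them.
#' @param path CSV file.
#' @return \code{path} (write) or a data.frame (read).
#' @export
write_count_series <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_series
#' @export
read_count_series <- function(path) {
  if (!file.exists(path)) stop("count series not found: ", path)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "count", "replicate_id")
  if (!all(need %in% names(out)))
    stop("count series CSV must have columns: ", paste(need, collapse = ", "))
  out
}

#' Store / load a mass calibration as JSON
#' @param cal a \code{MassCalibration}.
#' @param path JSON file.
#' @return \code{path} (write) or a \code{MassCalibration} (read).
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "MassCalibration"))
  obj <- list(slope = cal$slope, intercept = cal$intercept,
              slope_se = cal$slope_se, intercept_se = cal$intercept_se,
              cov = cal$cov, points = cal$points)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(slope = obj$slope, intercept = obj$intercept,
                 slope_se = obj$slope_se, intercept_se = obj$intercept_se,
                 cov = matrix(unlist(obj$cov), 2, 2),
                 points = as.data.frame(obj$points)),
            class = "MassCalibration")
}

#' Write a BGP fit as JSON
#' @param fit a \code{BGPFit}.
#' @param path JSON file.
#' @return \code{path}, invisibly.
#' @export
write_bgp_fit <- function(fit, path) {
  stopifnot(inherits(fit, "BGPFit"))
  obj <- list(t_grid = fit$t_grid, post_mean = fit$post_mean,
              post_sd = fit$post_sd, hyper_summary = fit$hyper_summary,
              diagnostics = fit$diagnostics, transform = fit$transform,
              monotone_projection = fit$monotone_projection,
              n_replicates = fit$n_replicates)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Loads the nested configuration (sections \code{synthdata},
#' \code{detect}, \code{classify}, \code{bgp}, \code{quantify},
#' \code{conditions}, \code{io}) used by \code{\link{run_pipeline}}. A
#' mandatory top-level \code{seed} governs every stochastic stage.
#'
#' @param path YAML file.
#' @return nested list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must set a seed")
  cfg
}

#' Hash a configuration for the run manifest
#' @param config nested list.
#' @return md5 hex string of the serialized configuration.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf))
  saveRDS(config, tf, version = 2)
  unname(tools::md5sum(tf))
}
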