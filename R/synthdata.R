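#' Binding-kinetics parameters
#'
#' Parameters of the first-order association model that drives the synthetic
#' assay. The cumulative number of detection-antibody binding events is the
#' integral of the instantaneous binding rate \eqn{k_{on} [A]_t [P]_t}, where
#' \eqn{[A]_t} is the concentration of free captured-analyte sites and
#' \eqn{[P]_t} the detection-antibody concentration (held constant under
#' continuous flow). To make the integral realizable as a discrete event
#' process, the analyte concentration is mapped to a finite number of
#' capturable sites inside the field of view: \eqn{[A]_t} is proportional to
#' the unoccupied fraction of \code{fov_site_count} sites.
#'
#' @param k_on association rate constant (per molar per second); >= 0.
#' @param analyte_conc molar concentration of captured analyte available at
#'   time zero; >= 0.
#' @param probe_conc molar detection-antibody concentration, constant over the
#'   record (continuous flow delivery); >= 0.
#' @param fov_site_count number of capturable analyte sites inside the field
#'   of view. \code{Inf} disables site depletion, in which case the expected
#'   count is exactly linear in time.
#' @param k_off dissociation rate constant (per second); 0 means bound probes
#'   never leave and each site yields at most one event.
#' @param duration record length in seconds; > 0.
#' @return A \code{KineticsParams} object.
#' @export
kinetics_params <- function(k_on, analyte_conc, probe_conc,
                            fov_site_count = Inf, k_off = 0, duration = 600) {
  vals <- c(k_on = k_on, analyte_conc = analyte_conc, probe_conc = probe_conc,
            k_off = k_off)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("rates and concentrations must be finite and >= 0")
  if (fov_site_count < 0) stop("fov_site_count must be >= 0")
  if (is.finite(fov_site_count) && fov_site_count != round(fov_site_count))
    stop("fov_site_count must be an integer (or Inf)")
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  structure(list(k_on = k_on, analyte_conc = analyte_conc,
                 probe_conc = probe_conc, fov_site_count = fov_site_count,
                 k_off = k_off, duration = duration),
            class = "KineticsParams")
}

#' Imaging and noise parameters of the synthetic video
#'
#' Forward-model parameters for rendering binding events into a plasmonic
#' scattering image stack. Spot amplitude is linear in molecular weight
#' (\code{intensity_offset + intensity_per_kda * mass}), the point-spread
#' function is an isotropic 2D Gaussian, and noise combines Poisson shot
#' noise on the total intensity with Gaussian read noise. The default
#' intensity scale is chosen so a 150 kDa antibody spot has amplitude about
#' five times the per-pixel noise sd of a differential frame produced with
#' the default 10-frame block average.
#'
#' @param psf_sigma Gaussian point-spread sd in pixels; > 0.
#' @param pixel_size nm per pixel (metadata).
#' @param frame_interval seconds per raw camera frame; > 0.
#' @param intensity_per_kda image counts per kDa of bound mass; > 0.
#' @param intensity_offset image counts added to every spot amplitude.
#' @param background_level mean background level in counts.
#' @param background_drift_rate fractional background change per second
#'   (linear drift; 0 keeps the background static).
#' @param speckle_fraction relative sd of a static low-frequency speckle
#'   field multiplying the background (0 disables it).
#' @param read_noise_sd Gaussian read noise sd in counts.
#' @param shot_noise logical; apply Poisson noise to the total signal.
#' @return An \code{OpticsParams} object.
#' @export
optics_params <- function(psf_sigma = 1.5, pixel_size = 100,
                          frame_interval = 0.001, intensity_per_kda = 0.47,
                          intensity_offset = 0, background_level = 1000,
                          background_drift_rate = 0, speckle_fraction = 0.2,
                          read_noise_sd = 3, shot_noise = TRUE) {
  if (psf_sigma <= 0) stop("psf_sigma must be > 0")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (intensity_per_kda <= 0) stop("intensity_per_kda must be > 0")
  if (background_level < 0) stop("background_level must be >= 0")
  structure(list(psf_sigma = psf_sigma, pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 intensity_per_kda = intensity_per_kda,
                 intensity_offset = intensity_offset,
                 background_level = background_level,
                 background_drift_rate = background_drift_rate,
                 speckle_fraction = speckle_fraction,
                 read_noise_sd = read_noise_sd,
                 shot_noise = isTRUE(shot_noise)),
            class = "OpticsParams")
}

#' Nonspecific-event configuration for the simulator
#'
#' Two nonspecific populations are generated. Sticky-site events re-occur at
#' a shared surface location (the repeated-location signature used to flag
#' nonspecific binding); their mass equals the detection antibody, so only
#' their binding frequency distinguishes them. Wrong-mass events appear once
#' at random locations with molecular weight drawn outside the
#' detection-antibody mass window.
#'
#' @param sticky_sites number of sticky surface sites.
#' @param sticky_visits binding events per sticky site (>= 2 so the site
#'   re-occurs within the record).
#' @param sticky_mass_kda molecular weight of sticky binders (defaults to an
#'   IgG-like 150 kDa).
#' @param sticky_dwell_s mean dwell of a sticky visit in seconds.
#' @param mass_events number of wrong-mass events over the record.
#' @param mass_ranges list of (low, high) kDa intervals from which wrong-mass
#'   molecular weights are drawn uniformly (one interval picked per event).
#' @return A \code{NonspecificConfig} object.
#' @export
nonspecific_config <- function(sticky_sites = 0, sticky_visits = 3,
                               sticky_mass_kda = 150, sticky_dwell_s = 0.05,
                               mass_events = 0,
                               mass_ranges = list(c(10, 50), c(300, 600))) {
  if (sticky_sites > 0 && sticky_visits < 2)
    stop("sticky_visits must be >= 2 (a sticky site re-occurs)")
  structure(list(sticky_sites = as.integer(sticky_sites),
                 sticky_visits = as.integer(sticky_visits),
                 sticky_mass_kda = sticky_mass_kda,
                 sticky_dwell_s = sticky_dwell_s,
                 mass_events = as.integer(mass_events),
                 mass_ranges = mass_ranges),
            class = "NonspecificConfig")
}

#' Expected cumulative binding counts under first-order kinetics
#'
#' Evaluates the kinetic forward model \eqn{N(T) = \int_0^T k_{on} [A]_t
#' [P]_t \, dt} on a time grid. With a finite site count S the free-analyte
#' term depletes with occupancy: writing r = k_on * probe_conc for the
#' per-site binding rate, the bound-site count B obeys
#' dB/dt = r (S - B) - k_off B and new binding events accrue as
#' dN/dt = r (S - B). Both equations admit a closed form, which is what this
#' function evaluates; with k_off > 0 the count keeps growing linearly after
#' occupancy equilibrates, which is the real-time assay's advantage over
#' endpoint counting. With \code{fov_site_count = Inf} depletion is disabled
#' and N(T) = k_on * analyte_conc * probe_conc * T exactly.
#'
#' @param kin a \code{KineticsParams} object.
#' @param t_grid numeric vector of times (seconds), starting at 0 and
#'   strictly increasing.
#' @return numeric vector of expected cumulative counts N(t), same length as
#'   \code{t_grid}; non-decreasing with N(0) = 0.
#' @export
expected_counts <- function(kin, t_grid) {
  stopifnot(inherits(kin, "KineticsParams"))
  if (length(t_grid) == 0L) stop("empty time grid")
  if (t_grid[1] != 0) stop("t_grid must start at 0")
  if (length(t_grid) > 1L && any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing")
  if (kin$analyte_conc == 0 || kin$k_on == 0 || kin$probe_conc == 0)
    return(numeric(length(t_grid)))
  if (!is.finite(kin$fov_site_count))
    return(kin$k_on * kin$analyte_conc * kin$probe_conc * t_grid)
  S <- kin$fov_site_count
  if (S == 0) return(numeric(length(t_grid)))
  r <- kin$k_on * kin$probe_conc
  g <- r + kin$k_off
  # N(t) = r*S*t - r * integral of B; B(t) = S*r/g*(1 - exp(-g t))
  em <- exp(-g * t_grid)
  S * r * (t_grid * (1 - r / g) + (r / g) * (1 - em) / g)
}

#' Sample ground-truth binding events
#'
#' Draws specific binding events as the discrete event process whose mean is
#' \code{\link{expected_counts}}: each of the \code{fov_site_count} surface
#' sites binds after an exponential waiting time with per-site rate
#' \code{k_on * probe_conc}, dwells exponentially with rate \code{k_off}
#' (forever if \code{k_off = 0}) and, once released, can bind again. With an
#' infinite site count a homogeneous Poisson process of rate
#' \code{k_on * analyte_conc * probe_conc} is used instead. Nonspecific
#' sticky-site and wrong-mass events are appended per \code{nonspecific}.
#'
#' @param kin a \code{KineticsParams} object.
#' @param opt an \code{OpticsParams} object (supplies the PSF sd used for the
#'   field-of-view margin).
#' @param nonspecific a \code{NonspecificConfig} object.
#' @param seed integer seed; the same seed reproduces the event table
#'   exactly. The global RNG state is left untouched.
#' @param fov_px integer (rows, cols) extent of the field of view in pixels.
#' @param antibody_mass_kda molecular weight of the specific binder.
#' @return data.frame with columns \code{event_id}, \code{site_id},
#'   \code{x_px}, \code{y_px} (0-based, pixel-center convention),
#'   \code{t_on_s}, \code{t_off_s}, \code{mass_kda}, \code{label}
#'   (\code{specific}, \code{nonspecific_sticky} or
#'   \code{nonspecific_mass}), ordered by arrival time.
#' @export
sample_events <- function(kin, opt, nonspecific = nonspecific_config(),
                          seed, fov_px = c(256L, 256L),
                          antibody_mass_kda = 150) {
  stopifnot(inherits(kin, "KineticsParams"), inherits(opt, "OpticsParams"),
            inherits(nonspecific, "NonspecificConfig"))
  if (missing(seed)) stop("seed is required for reproducibility")
  withr::with_seed(as.integer(seed), {
    margin <- ceiling(4 * opt$psf_sigma)
    min_sep <- 2 * opt$psf_sigma
    ## surface sites are resolvable: pairwise separation of at least two
    ## PSF sigmas, so ground-truth labels remain meaningful to a detector
    ## that defines "the same location" at the localization scale. Beyond
    ## a packing limit (dense regimes are unresolvable by construction)
    ## separation is no longer enforced.
    usable <- (fov_px[1] - 1 - 2 * margin) * (fov_px[2] - 1 - 2 * margin)
    sep_cap <- max(floor(0.25 * usable / min_sep^2), 1L)
    placed_x <- numeric(0); placed_y <- numeric(0)
    rand_xy <- function(n) {
      out <- matrix(0, n, 2, dimnames = list(NULL, c("x", "y")))
      for (i in seq_len(n)) {
        enforce <- length(placed_x) < sep_cap
        for (try in 1:40) {
          x <- runif(1, margin, fov_px[2] - 1 - margin)
          y <- runif(1, margin, fov_px[1] - 1 - margin)
          if (!enforce || length(placed_x) == 0L ||
              all((x - placed_x)^2 + (y - placed_y)^2 >= min_sep^2)) break
        }
        placed_x <<- c(placed_x, x); placed_y <<- c(placed_y, y)
        out[i, ] <- c(x, y)
      }
      out
    }
    T_end <- kin$duration
    rows <- list()

    ## specific arrivals
    if (kin$analyte_conc > 0 && kin$k_on > 0 && kin$probe_conc > 0 &&
        kin$fov_site_count > 0) {
      if (is.finite(kin$fov_site_count)) {
        r <- kin$k_on * kin$probe_conc
        for (s in seq_len(kin$fov_site_count)) {
          first_on <- rexp(1L, r)
          if (first_on >= T_end) next   # site never binds; no location needed
          xy <- rand_xy(1L)
          t_cur <- 0; first <- TRUE
          repeat {
            t_on <- if (first) first_on else t_cur + rexp(1L, r)
            first <- FALSE
            if (t_on >= T_end) break
            dwell <- if (kin$k_off > 0) rexp(1L, kin$k_off) else Inf
            t_off <- min(t_on + dwell, T_end)
            rows[[length(rows) + 1L]] <- data.frame(
              site_id = s, x_px = xy[1, "x"], y_px = xy[1, "y"],
              t_on_s = t_on, t_off_s = t_off,
              mass_kda = antibody_mass_kda, label = "specific")
            if (!is.finite(dwell) || t_off >= T_end) break
            t_cur <- t_off
          }
        }
      } else {
        lambda <- kin$k_on * kin$analyte_conc * kin$probe_conc
        n <- rpois(1L, lambda * T_end)
        if (n > 0) {
          t_on <- sort(runif(n, 0, T_end))
          dwell <- if (kin$k_off > 0) rexp(n, kin$k_off) else rep(Inf, n)
          xy <- rand_xy(n)
          rows[[length(rows) + 1L]] <- data.frame(
            site_id = seq_len(n) + 10^6, x_px = xy[, "x"], y_px = xy[, "y"],
            t_on_s = t_on, t_off_s = pmin(t_on + dwell, T_end),
            mass_kda = antibody_mass_kda, label = "specific")
        }
      }
    }

    ## sticky sites: >= 2 visits at a shared location, spread as separated
    ## excursions (one visit per equal segment of the record) so re-binding
    ## at the site is temporally resolvable
    if (nonspecific$sticky_sites > 0) {
      k <- nonspecific$sticky_visits
      seg <- T_end / k
      for (s in seq_len(nonspecific$sticky_sites)) {
        xy <- rand_xy(1L)
        t_on <- (seq_len(k) - 1) * seg + runif(k, 0.05 * seg, 0.55 * seg)
        dwell <- pmax(rexp(k, 1 / nonspecific$sticky_dwell_s), 1e-6)
        t_off <- pmin(t_on + dwell, seq_len(k) * seg - 0.05 * seg)
        rows[[length(rows) + 1L]] <- data.frame(
          site_id = -s, x_px = rep(xy[1, "x"], k), y_px = rep(xy[1, "y"], k),
          t_on_s = t_on, t_off_s = t_off,
          mass_kda = nonspecific$sticky_mass_kda, label = "nonspecific_sticky")
      }
    }

    ## wrong-mass events at fresh locations
    if (nonspecific$mass_events > 0) {
      n <- nonspecific$mass_events
      xy <- rand_xy(n)
      pick <- sample.int(length(nonspecific$mass_ranges), n, replace = TRUE)
      mass <- vapply(pick, function(i) {
        rg <- nonspecific$mass_ranges[[i]]
        runif(1L, rg[1], rg[2])
      }, numeric(1))
      t_on <- runif(n, 0, T_end * 0.95)
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = -(nonspecific$sticky_sites + seq_len(n)),
        x_px = xy[, "x"], y_px = xy[, "y"],
        t_on_s = t_on, t_off_s = rep(T_end, n),
        mass_kda = mass, label = "nonspecific_mass")
    }

    if (length(rows) == 0L) {
      return(data.frame(event_id = integer(0), site_id = integer(0),
                        x_px = numeric(0), y_px = numeric(0),
                        t_on_s = numeric(0), t_off_s = numeric(0),
                        mass_kda = numeric(0), label = character(0)))
    }
    ev <- do.call(rbind, rows)
    ev <- ev[order(ev$t_on_s), , drop = FALSE]
    ev <- cbind(event_id = seq_len(nrow(ev)), ev)
    rownames(ev) <- NULL
    ev
  })
}

## Gaussian blob added in place into `img` at 0-based sub-pixel (x, y)
add_gaussian <- function(img, x, y, amplitude, sigma) {
  w <- ceiling(4 * sigma)
  nr <- nrow(img); nc <- ncol(img)
  rows <- max(1L, floor(y) - w + 1L):min(nr, ceiling(y) + w + 1L)
  cols <- max(1L, floor(x) - w + 1L):min(nc, ceiling(x) + w + 1L)
  gy <- exp(-((rows - 1 - y)^2) / (2 * sigma^2))
  gx <- exp(-((cols - 1 - x)^2) / (2 * sigma^2))
  img[rows, cols] <- img[rows, cols] + amplitude * outer(gy, gx)
  img
}

## static low-frequency speckle field, mean 1, relative sd ~= fraction
speckle_field <- function(nr, nc, fraction, coarse = 8L) {
  if (fraction <= 0) return(matrix(1, nr, nc))
  g <- matrix(rnorm(coarse * coarse), coarse, coarse)
  f <- EBImage::resize(g, w = nr, h = nc)
  f <- (f - mean(f)) / stats::sd(f)
  pmax(1 + fraction * f, 0.05)
}

#' Render ground-truth events into a synthetic image stack
#'
#' Forward model of the plasmonic scattering video: a bright background
#' (optionally with static speckle structure and a linear fractional drift)
#' plus, for every event active in a frame, a 2D Gaussian of sd
#' \code{psf_sigma} and amplitude \code{intensity_offset +
#' intensity_per_kda * mass_kda}. An event is active in a raw frame when its
#' [t_on, t_off) interval covers the frame midpoint. Poisson shot noise on
#' the total intensity and Gaussian read noise are applied per
#' \code{opt}; pixel values are clamped at 0.
#'
#' @param events event table as returned by \code{\link{sample_events}}.
#' @param opt an \code{OpticsParams} object.
#' @param shape integer (frames, rows, cols); frames >= 2.
#' @param seed integer seed for the noise draws; identical seeds give
#'   bit-identical stacks.
#' @return list with \code{stack} (a raw \code{FrameStack}) and
#'   \code{annotation} (events with first/last active raw frame, 0-based,
#'   -1 when never active).
#' @export
render_stack <- function(events, opt, shape, seed = 1L) {
  stopifnot(inherits(opt, "OpticsParams"), length(shape) == 3L)
  nf <- shape[1]; nr <- shape[2]; nc <- shape[3]
  if (nf < 2L) stop("frame count must be >= 2")
  if (nrow(events) > 0) {
    bad <- which(events$x_px < 0 | events$x_px > nc - 1 |
                 events$y_px < 0 | events$y_px > nr - 1)
    if (length(bad))
      stop(sprintf("event(s) outside field of view: %s",
                   paste(events$event_id[bad], collapse = ", ")))
  }
  dt <- opt$frame_interval
  withr::with_seed(as.integer(seed), {
    speck <- speckle_field(nr, nc, opt$speckle_fraction)
    base_bg <- opt$background_level * speck
    pixels <- array(0, dim = c(nf, nr, nc))
    t_mid <- (seq_len(nf) - 0.5) * dt
    amp <- opt$intensity_offset + opt$intensity_per_kda * events$mass_kda
    first_f <- rep(-1L, nrow(events)); last_f <- rep(-1L, nrow(events))
    for (f in seq_len(nf)) {
      img <- base_bg * (1 + opt$background_drift_rate * t_mid[f])
      act <- which(events$t_on_s <= t_mid[f] & events$t_off_s > t_mid[f])
      for (i in act) {
        img <- add_gaussian(img, events$x_px[i], events$y_px[i], amp[i],
                            opt$psf_sigma)
        if (first_f[i] < 0L) first_f[i] <- f - 1L
        last_f[i] <- f - 1L
      }
      if (opt$shot_noise)
        img <- matrix(rpois(nr * nc, pmax(img, 0)), nr, nc)
      if (opt$read_noise_sd > 0)
        img <- img + matrix(rnorm(nr * nc, 0, opt$read_noise_sd), nr, nc)
      pixels[f, , ] <- pmax(img, 0)
    }
    ann <- cbind(events,
                 frame_on = first_f, frame_off = last_f)
    list(stack = frame_stack(pixels, dt, opt$pixel_size, "raw"),
         annotation = ann)
  })
}
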