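#' Dynamic-instability parameter set
#'
#' Rates of the two-state (growth/shrinkage) dynamic instability model
#' with stochastic nucleation from a stabilized seed. All rates are per
#' minute, velocities in micrometers per minute.
#'
#' @param v_g growth velocity, um/min.
#' @param v_s shrinkage velocity (magnitude), um/min.
#' @param f_cat catastrophe frequency during growth, events/min.
#' @param f_res rescue frequency during shrinkage, events/min.
#' @param k_nuc nucleation rate at the seed, events/min.
#' @param seed_length GMPCPP seed length, um (rendering only; tip
#'   positions are measured from the seed's distal end).
#' @return object of class \code{di_params}.
#' @examples
#' di_params(v_g = 1.2, f_cat = 0.25)
#' @export
di_params <- function(v_g = 1.2, v_s = 6.0, f_cat = 0.25, f_res = 0.5,
                      k_nuc = 0.3, seed_length = 2.0) {
  p <- list(v_g = v_g, v_s = v_s, f_cat = f_cat, f_res = f_res,
            k_nuc = k_nuc, seed_length = seed_length)
  if (any(!vapply(p, is.finite, TRUE) & !vapply(p, function(x) identical(x, Inf), TRUE)))
    stop("all parameters must be numeric")
  if (any(unlist(p) < 0)) stop("rates and lengths must be >= 0")
  if (v_g <= 0 || v_s <= 0) stop("v_g and v_s must be > 0")
  structure(p, class = "di_params")
}

#' @export
print.di_params <- function(x, ...) {
  cat(sprintf(paste0("Dynamic instability parameters:\n",
                     "  v_g %.2f um/min, v_s %.2f um/min\n",
                     "  f_cat %.3f /min, f_res %.3f /min, k_nuc %.3f /min\n",
                     "  seed length %.1f um\n"),
              x$v_g, x$v_s, x$f_cat, x$f_res, x$k_nuc, x$seed_length))
  invisible(x)
}

.rexp_or_inf <- function(rate) if (rate > 0) stats::rexp(1L, rate) else Inf

#' Simulate two-state dynamic instability at the acquisition frame rate
#'
#' Events are resolved in continuous time - exponential waiting times
#' for nucleation (clock starts when the polymerization mix is
#' introduced, between frames \code{mix_frame - 1} and \code{mix_frame}),
#' catastrophe during growth and rescue during shrinkage, with
#' deterministic velocities between events - and then sampled at the
#' frame times. A tip that shrinks back to the seed (position 0) returns
#' to the pre-nucleation state and, if \code{renucleate}, waits for a new
#' nucleation event.
#'
#' @param params a \code{\link{di_params}} set.
#' @param n_frames number of movie frames.
#' @param frame_interval seconds per frame.
#' @param seed RNG seed.
#' @param mix_frame frame at which the polymerization mix arrives; the
#'   nucleation clock starts at \code{(mix_frame - 1) * frame_interval}.
#' @param renucleate allow repeated nucleation from the same seed after
#'   complete depolymerization.
#' @param initial_phase phase at time zero: \code{"pre"} (default, empty
#'   seed), \code{"growth"} or \code{"shrinkage"} (with
#'   \code{initial_length}); non-default initial states are useful for
#'   single-excursion experiments.
#' @param initial_length tip position at time zero, um, for non-default
#'   \code{initial_phase}.
#' @return object of class \code{event_trace}: list with \code{frames}
#'   (data frame \code{frame}, \code{time_s}, \code{tip_um},
#'   \code{phase}), \code{events} (data frame \code{time_s},
#'   \code{type}, \code{tip_um}), \code{params} and the acquisition
#'   settings.
#' @examples
#' tr <- simulate_dynamics(di_params(), seed = 1)
#' table(tr$frames$phase)
#' @export
simulate_dynamics <- function(params, n_frames = 180L, frame_interval = 10,
                              seed = NULL, mix_frame = 2L, renucleate = TRUE,
                              initial_phase = c("pre", "growth", "shrinkage"),
                              initial_length = 0) {
  stopifnot(inherits(params, "di_params"))
  initial_phase <- match.arg(initial_phase)
  if (!is.null(seed)) set.seed(as.integer(seed))
  dt <- frame_interval / 60                    # minutes
  t_end <- (n_frames - 1L) * dt
  t_mix <- (mix_frame - 1L) * dt

  ## piecewise phases: list of (t0, t1, phase, pos0, slope)
  phases <- list()
  events <- list()
  add_event <- function(t, type, pos) {
    events[[length(events) + 1L]] <<- data.frame(time_s = t * 60, type = type,
                                                 tip_um = pos)
  }
  add_phase <- function(t0, t1, phase, pos0, slope) {
    phases[[length(phases) + 1L]] <<- list(t0 = t0, t1 = t1, phase = phase,
                                           pos0 = pos0, slope = slope)
  }

  t <- 0; pos <- 0; state <- "pre"
  if (initial_phase != "pre") {
    state <- initial_phase
    pos <- initial_length
  } else if (t_mix > 0) {
    add_phase(0, min(t_mix, t_end), "pre-nucleation", 0, 0)
    t <- t_mix
  }

  while (t < t_end) {
    if (state == "pre") {
      w <- .rexp_or_inf(params$k_nuc)
      if (t + w >= t_end) { add_phase(t, t_end, "pre-nucleation", 0, 0); break }
      add_phase(t, t + w, "pre-nucleation", 0, 0)
      t <- t + w
      add_event(t, "nucleation", 0)
      state <- "growth"; pos <- 0
    } else if (state == "growth") {
      w <- .rexp_or_inf(params$f_cat)
      t1 <- min(t + w, t_end)
      add_phase(t, t1, "growth", pos, params$v_g)
      pos <- pos + params$v_g * (t1 - t)
      t <- t1
      if (t >= t_end) break
      add_event(t, "catastrophe", pos)
      state <- "shrinkage"
    } else {                                   # shrinkage
      w <- .rexp_or_inf(params$f_res)
      t_seed <- pos / params$v_s               # time to reach the seed
      if (w < t_seed) {
        t1 <- min(t + w, t_end)
        add_phase(t, t1, "shrinkage", pos, -params$v_s)
        pos <- pos - params$v_s * (t1 - t)
        t <- t1
        if (t >= t_end) break
        add_event(t, "rescue", pos)
        state <- "growth"
      } else {
        t1 <- min(t + t_seed, t_end)
        add_phase(t, t1, "shrinkage", pos, -params$v_s)
        pos <- max(0, pos - params$v_s * (t1 - t))
        t <- t1
        if (t >= t_end) break
        add_event(t, "reach_seed", 0)
        pos <- 0
        state <- "pre"
        if (!renucleate) { add_phase(t, t_end, "pre-nucleation", 0, 0); break }
      }
    }
  }

  ## sample at frame times
  ft <- (seq_len(n_frames) - 1L) * dt
  tip <- numeric(n_frames)
  ph <- character(n_frames)
  pi_ <- 1L
  for (i in seq_len(n_frames)) {
    while (pi_ < length(phases) && ft[i] > phases[[pi_]]$t1 + 1e-12) pi_ <- pi_ + 1L
    p <- phases[[pi_]]
    tip[i] <- max(0, p$pos0 + p$slope * (ft[i] - p$t0))
    ph[i] <- p$phase
  }
  ev <- if (length(events)) do.call(rbind, events)
        else data.frame(time_s = numeric(0), type = character(0), tip_um = numeric(0))

  structure(list(
    frames = data.frame(frame = seq_len(n_frames), time_s = ft * 60,
                        tip_um = tip, phase = ph),
    events = ev,
    params = params,
    n_frames = n_frames, frame_interval = frame_interval, mix_frame = mix_frame
  ), class = "event_trace")
}

#' @export
print.event_trace <- function(x, ...) {
  cat(sprintf("Dynamic instability trace: %d frames at %.0f s/frame (%.1f min)\n",
              x$n_frames, x$frame_interval,
              x$n_frames * x$frame_interval / 60))
  tb <- table(x$frames$phase)
  cat("  frames per phase:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  %d events; max tip %.2f um\n", nrow(x$events), max(x$frames$tip_um)))
  invisible(x)
}

#' @export
plot.event_trace <- function(x, ...) {
  graphics::plot(x$frames$time_s / 60, x$frames$tip_um, type = "l",
                 xlab = "time (min)", ylab = "tip position (um)", ...)
  if (nrow(x$events))
    graphics::abline(v = x$events$time_s[x$events$type == "catastrophe"] / 60,
                     col = "grey70", lty = 3)
  invisible(x)
}

#' Render a TIRF-style kymograph from a simulated trace
#'
#' Each movie frame paints one image row: the seed segment plus the
#' microtubule from the seed's distal edge to the current tip, convolved
#' with a Gaussian line-spread function and overlaid with Gaussian
#' noise. SNR is defined as line amplitude / noise SD.
#'
#' @param trace an \code{\link{simulate_dynamics}} result.
#' @param pixel_size um per pixel.
#' @param psf_sigma line-spread SD in pixels (0 for none).
#' @param snr amplitude-to-noise ratio; \code{Inf} for noise-free.
#' @param seed RNG seed for the noise.
#' @param field_um field of view along the microtubule, um; default
#'   fits the largest excursion plus a margin.
#' @return object of class \code{kymograph}: list with \code{image}
#'   (matrix, rows = frames), \code{pixel_size}, \code{frame_interval},
#'   \code{seed_extent} (seed length in px).
#' @export
render_kymograph <- function(trace, pixel_size = 0.1, psf_sigma = 1,
                             snr = Inf, seed = NULL, field_um = NULL) {
  stopifnot(inherits(trace, "event_trace"))
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  seed_um <- trace$params$seed_length
  need <- seed_um + max(trace$frames$tip_um) + 10 * pixel_size
  if (is.null(field_um)) field_um <- need
  if (field_um < need)
    stop(sprintf("field_um %.1f too short for the maximal excursion; need >= %.1f um",
                 field_um, need))
  npx <- ceiling(field_um / pixel_size)
  seed_px <- round(seed_um / pixel_size)
  nf <- trace$n_frames
  img <- matrix(0, nf, npx)
  xc <- (seq_len(npx) - 0.5) * pixel_size          # pixel centers, um
  for (i in seq_len(nf)) {
    img[i, xc < seed_um + trace$frames$tip_um[i]] <- 1
  }
  if (psf_sigma > 0) {
    w <- ceiling(4 * psf_sigma)
    k <- stats::dnorm(-w:w, sd = psf_sigma)
    k <- k / sum(k)
    pad <- matrix(0, nf, w)
    ext <- cbind(pad, img, pad)
    img <- t(apply(ext, 1L, function(row) stats::convolve(row, rev(k), type = "filter")))
  }
  if (is.finite(snr)) {
    if (snr <= 0) stop("snr must be > 0")
    img <- img + matrix(stats::rnorm(length(img), sd = 1 / snr), nrow(img))
  }
  structure(list(image = img, pixel_size = pixel_size,
                 frame_interval = trace$frame_interval,
                 seed_extent = seed_px),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("Kymograph: %d frames x %d px, %.2f um/px, %.0f s/frame, seed %d px\n",
              nrow(x$image), ncol(x$image), x$pixel_size, x$frame_interval,
              x$seed_extent))
  invisible(x)
}

#' @export
plot.kymograph <- function(x, ...) {
  graphics::image(x = (seq_len(ncol(x$image)) - 0.5) * x$pixel_size,
                  y = (seq_len(nrow(x$image)) - 1) * x$frame_interval / 60,
                  z = t(x$image[nrow(x$image):1, ]),
                  col = grDevices::gray.colors(64, 0, 1),
                  xlab = "position (um)", ylab = "time (min)", useRaster = TRUE, ...)
  invisible(x)
}
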