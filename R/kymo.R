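#' Trace the microtubule tip through a kymograph
#'
#' Per image row (frame), the tip is the farthest pixel above an
#' Otsu-derived intensity threshold that is contiguous with the seed;
#' the resulting trace is median-filtered over 3 frames. Tip positions
#' are reported in pixels from the seed's distal edge.
#'
#' @param kymo a \code{\link{render_kymograph}} result, or a plain
#'   matrix (rows = frames) with \code{seed_extent} supplied.
#' @param seed_extent seed length in pixels (taken from the kymograph
#'   object when available).
#' @param max_gap sub-threshold gaps up to this many pixels are bridged
#'   when walking out from the seed (isolated noise dropouts must not
#'   truncate the tip).
#' @param median_frames width of the temporal median window (odd; 1
#'   disables the filter).
#' @param despike_px a frame is replaced by its running median only if
#'   it deviates from both neighbours by more than this, in opposite
#'   directions (an isolated mis-traced row); genuine phase corners are
#'   left untouched.
#' @return object of class \code{tip_trace}: data frame \code{frame},
#'   \code{tip_px}; attributes \code{pixel_size}, \code{frame_interval},
#'   \code{provenance}.
#' @export
trace_tip <- function(kymo, seed_extent = NULL, max_gap = 2L, median_frames = 3L,
                      despike_px = 5) {
  if (inherits(kymo, "kymograph")) {
    img <- kymo$image
    if (is.null(seed_extent)) seed_extent <- kymo$seed_extent
    px <- kymo$pixel_size; fi <- kymo$frame_interval
  } else {
    img <- as.matrix(kymo)
    px <- NA_real_; fi <- NA_real_
  }
  if (is.null(seed_extent)) stop("seed_extent is required")
  if (nrow(img) < 10L) stop("kymograph must have at least 10 frames")

  rng <- range(img)
  if (diff(rng) <= 0) stop("no microtubule detected")
  ## light lateral smoothing before thresholding: averages down pixel
  ## noise without moving edges more than a constant offset
  if (ncol(img) >= 3L) {
    sm <- img
    sm[, 2:(ncol(img) - 1L)] <- (img[, 1:(ncol(img) - 2L)] +
                                 img[, 2:(ncol(img) - 1L)] +
                                 img[, 3:ncol(img)]) / 3
    img <- sm
  }
  rng <- range(img)
  norm <- (img - rng[1L]) / diff(rng)
  thr <- EBImage::otsu(norm, range = c(0, 1))
  bin <- norm > thr
  tip <- numeric(nrow(img))
  n_signal <- 0L
  start <- max(1L, round(seed_extent / 2))     # mid-seed: clear of edge roll-off
  for (i in seq_len(nrow(img))) {
    row <- bin[i, start:ncol(img)]
    if (!row[1L]) { tip[i] <- 0; next }       # not contiguous with the seed
    gaps <- rle(row)
    ends <- cumsum(gaps$lengths)
    stop_at <- which(!gaps$values & gaps$lengths > max_gap)
    last <- if (length(stop_at)) ends[stop_at[1L]] - gaps$lengths[stop_at[1L]]
            else { filled <- ends[gaps$values]; filled[length(filled)] }
    n_signal <- n_signal + 1L
    tip[i] <- last + start - 1L - seed_extent
  }
  if (n_signal < 0.1 * nrow(img)) stop("no microtubule detected")
  ## the immobilized seed must be consistently bright; pure noise passes
  ## the threshold only in scattered pixels
  seed_cols <- max(1L, start):max(1L, seed_extent - 2L)
  if (mean(bin[, seed_cols]) < 0.8) stop("no microtubule detected")
  if (median_frames > 1L) {
    ## conditional median: only two-sided spikes (tracing dropouts or
    ## bridged noise) are replaced; real phase corners, where the two
    ## neighbouring steps disagree in sign but only one is large, stay
    med <- stats::runmed(tip, median_frames)
    nfr <- length(tip)
    if (nfr >= 3L) {
      d1 <- tip[2:(nfr - 1L)] - tip[1:(nfr - 2L)]
      d2 <- tip[3:nfr] - tip[2:(nfr - 1L)]
      spike <- d1 * d2 < 0 & pmin(abs(d1), abs(d2)) > despike_px
      tip[c(FALSE, spike, FALSE)] <- med[c(FALSE, spike, FALSE)]
    }
  }
  tip <- pmax(tip, 0)
  out <- data.frame(frame = seq_len(nrow(img)), tip_px = as.numeric(tip))
  attr(out, "pixel_size") <- px
  attr(out, "frame_interval") <- fi
  attr(out, "provenance") <- "auto"
  class(out) <- c("tip_trace", "data.frame")
  out
}

#' Construct a tip trace from frame/position pairs
#'
#' Wraps manually digitized kymograph coordinates (e.g. exported from
#' line fitting in an image viewer) as a first-class tip trace.
#'
#' @param tip_px numeric vector of per-frame tip positions, px from the
#'   seed's distal edge.
#' @param pixel_size optional um/px calibration.
#' @param frame_interval optional s/frame calibration.
#' @param provenance provenance tag.
#' @return a \code{tip_trace}.
#' @export
tip_trace <- function(tip_px, pixel_size = NA_real_, frame_interval = NA_real_,
                      provenance = "manual_csv") {
  out <- data.frame(frame = seq_along(tip_px), tip_px = as.numeric(tip_px))
  attr(out, "pixel_size") <- pixel_size
  attr(out, "frame_interval") <- frame_interval
  attr(out, "provenance") <- provenance
  class(out) <- c("tip_trace", "data.frame")
  out
}

#' Segment a tip trace into nucleating, growth and shrinkage phases
#'
#' Piecewise-linear segmentation by the sign of per-frame displacement:
#' intervals steeper than \code{slope_threshold} are growth (+) or
#' shrinkage (-), the rest nucleating/paused. Runs shorter than
#' \code{min_phase_frames} are absorbed into their longer neighbour. The
#' first triangle is the first growth phase together with its
#' terminating shrinkage phase; a trace that ends while still growing
#' has a censored triangle (no shrinkage limb).
#'
#' Phase slopes are fitted by least squares over the frames of the
#' phase, dropping the first and last frame of phases long enough to
#' afford it (event times fall between frames, so boundary frames may
#' belong partly to the neighbouring phase).
#'
#' @param trace a \code{tip_trace}.
#' @param min_phase_frames minimum frames per phase.
#' @param slope_threshold minimum |displacement| per frame (px) to count
#'   as growth or shrinkage.
#' @param seed_floor_px tip positions at or below this are treated as
#'   pinned at the seed and excluded from shrinkage slope fits.
#' @param min_event_px a run shorter than \code{min_phase_frames} is
#'   still kept as a phase if it displaces the tip by at least this many
#'   pixels (a sub-resolution catastrophe or rescue excursion).
#' @param hard_event_px a single-frame displacement at least this large
#'   overrides the smoothed labelling; it marks a real event even when
#'   the smoother dilutes it.
#' @return object of class \code{phase_segmentation}: list with
#'   \code{phases} (data frame \code{kind}, \code{start_frame},
#'   \code{end_frame}, \code{slope_px_per_frame}), \code{first_triangle}
#'   (list \code{growth}, \code{shrinkage} phase indices, possibly NA,
#'   and \code{censored} flag) and the trace.
#' @export
segment_phases <- function(trace, min_phase_frames = 3L, slope_threshold = 0.5,
                           seed_floor_px = 3, min_event_px = 4,
                           hard_event_px = 6) {
  stopifnot(inherits(trace, "tip_trace"))
  x <- trace$tip_px
  nf <- length(x)
  if (nf < 2L * min_phase_frames) stop("trace too short to segment")
  d <- diff(x)
  ## label phases on a median-smoothed copy (stable signs); fit slopes
  ## on the original values (sharp corners)
  xs <- if (nf >= 3L) stats::runmed(x, 3L) else x
  ds <- diff(xs)
  lab <- ifelse(ds > slope_threshold, 1L, ifelse(ds < -slope_threshold, -1L, 0L))
  ## the smoother dilutes one-interval excursions (e.g. a catastrophe
  ## followed by an immediate rescue); a strong raw displacement is an
  ## event regardless of the smoothed label
  strong <- abs(d) >= hard_event_px
  lab[strong] <- sign(d[strong])

  ## run-length encode, absorbing short runs into the longer neighbour;
  ## a short run that moves the tip a long way is a real event (e.g. a
  ## 1-frame catastrophe-and-rescue), not jitter, and is kept
  r <- rle(lab)
  repeat {
    len_frames <- r$lengths + 1L
    ends_r <- cumsum(r$lengths)
    disp <- abs(x[ends_r + 1L] - x[ends_r - r$lengths + 1L])
    short <- which(len_frames < min_phase_frames & r$lengths > 0 &
                   (r$values == 0L | disp < min_event_px))
    if (!length(short) || length(r$lengths) == 1L) break
    i <- short[which.min(r$lengths[short])]
    nb <- c(i - 1L, i + 1L)
    nb <- nb[nb >= 1L & nb <= length(r$lengths)]
    j <- nb[which.max(r$lengths[nb])]
    r$values[i] <- r$values[j]
    r <- rle(inverse.rle(r))
  }

  ## a short pause flanked by two runs of the same sign is segmentation
  ## noise inside one phase, not a real pause: merge it
  repeat {
    flat <- which(r$values == 0L & r$lengths <= 3L)
    flat <- flat[flat > 1L & flat < length(r$lengths)]
    flat <- flat[r$values[flat - 1L] == r$values[flat + 1L] & r$values[flat - 1L] != 0L]
    if (!length(flat)) break
    r$values[flat[1L]] <- r$values[flat[1L] - 1L]
    r <- rle(inverse.rle(r))
  }

  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  kinds <- c("shrinkage", "nucleating", "growth")[r$values + 2L]
  phases <- data.frame(
    kind = kinds,
    start_frame = starts,                       # first frame of the phase
    end_frame = ends + 1L,                      # last frame of the phase
    slope_px_per_frame = NA_real_
  )
  fit_slope <- function(ff) {
    if (length(ff) < 2L) return(d[ff[1L]])
    b <- stats::cov(ff, x[ff]) / stats::var(ff)
    if (length(ff) >= 5L) {
      ## one reweighting pass: drop gross tracing outliers
      res <- x[ff] - (mean(x[ff]) + b * (ff - mean(ff)))
      keep <- abs(res) <= max(3 * stats::mad(res), 2)
      if (sum(keep) >= 3L && !all(keep))
        b <- stats::cov(ff[keep], x[ff[keep]]) / stats::var(ff[keep])
    }
    b
  }
  for (i in seq_len(nrow(phases))) {
    f0 <- phases$start_frame[i]; f1 <- phases$end_frame[i]
    ## boundary frames can straddle an event; drop them when affordable
    if (f1 - f0 >= 3L) { f0 <- f0 + 1L; f1 <- f1 - 1L }
    ff <- f0:f1
    if (kinds[i] == "shrinkage") {
      ## a phase of fewer than 3 frames has no interval that is surely
      ## interior to the shrinkage: its net displacement mixes the
      ## flanking events and is not a rate measurement
      if (phases$end_frame[i] - phases$start_frame[i] < 2L) {
        phases$slope_px_per_frame[i] <- NA_real_
        next
      }
      ## a short phase keeps its first frame after the generic trim, but
      ## if the step into that frame was still growth-like the frame
      ## sits on the growth line (the catastrophe fell inside the next
      ## interval) and would dilute the shrinkage slope
      if (length(ff) >= 3L && ff[1L] > 1L && d[ff[1L] - 1L] > slope_threshold)
        ff <- ff[-1L]
      ## symmetric check at a rescue corner: a last frame whose outgoing
      ## step is growth-like lies on the regrowth line
      if (length(ff) >= 3L && ff[length(ff)] <= length(d) &&
          d[ff[length(ff)]] > slope_threshold)
        ff <- ff[-length(ff)]
      ## frames at the seed floor carry no slope information (PSF
      ## roll-off pins them near zero); a shrinkage phase without two
      ## clean frames has no measurable rate
      ff <- ff[x[ff] > seed_floor_px]
      phases$slope_px_per_frame[i] <- if (length(ff) >= 2L) fit_slope(ff) else NA_real_
    } else {
      phases$slope_px_per_frame[i] <- fit_slope(ff)
    }
  }

  g <- which(phases$kind == "growth")
  triangle <- list(growth = NA_integer_, shrinkage = NA_integer_, censored = FALSE)
  if (length(g)) {
    triangle$growth <- g[1L]
    if (g[1L] < nrow(phases) && phases$kind[g[1L] + 1L] == "shrinkage") {
      triangle$shrinkage <- g[1L] + 1L
    } else {
      triangle$censored <- TRUE
    }
  }
  structure(list(phases = phases, first_triangle = triangle, trace = trace),
            class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat(sprintf("Phase segmentation: %d phases\n", nrow(x$phases)))
  print.data.frame(x$phases, digits = 3)
  tr <- x$first_triangle
  if (is.na(tr$growth)) {
    cat("  no growth phase found (empty first triangle)\n")
  } else if (tr$censored) {
    cat(sprintf("  first triangle: growth phase %d, censored (movie ends mid-growth)\n",
                tr$growth))
  } else {
    cat(sprintf("  first triangle: growth phase %d, shrinkage phase %d\n",
                tr$growth, tr$shrinkage))
  }
  invisible(x)
}

#' Per-microtubule dynamics summary from the first triangle
#'
#' Converts the first-triangle segmentation into the standard dynamic
#' parameters: growth rate and shrinkage rate (um/min), maximal length
#' (um), lifetime (min, nucleation to first catastrophe) and nucleation
#' time (min, mix introduction to nucleation). A censored triangle
#' leaves the shrinkage rate missing (NA), not zero.
#'
#' @param seg a \code{\link{segment_phases}} result.
#' @param pixel_size um/px; defaults to the trace calibration.
#' @param frame_interval s/frame; defaults to the trace calibration.
#' @param mix_frame frame at which the polymerization mix arrived.
#' @param rescue_threshold_px threshold for true rescues (see
#'   \code{\link{classify_rescue}}).
#' @return object of class \code{mt_dynamics}: one-row data frame with
#'   \code{length_um}, \code{lifetime_min}, \code{growth_rate},
#'   \code{shrink_rate}, \code{nucleation_time_min}, \code{censored},
#'   plus attribute \code{rescue_events}.
#' @examples
#' tr <- simulate_dynamics(di_params(), seed = 1)
#' seg <- segment_phases(tip_trace(tr$frames$tip_um / 0.1))
#' compute_dynamics_summary(seg, pixel_size = 0.1, frame_interval = 10)
#' @export
compute_dynamics_summary <- function(seg, pixel_size = NULL, frame_interval = NULL,
                                     mix_frame = 2L, rescue_threshold_px = 5L) {
  stopifnot(inherits(seg, "phase_segmentation"))
  if (is.null(pixel_size)) pixel_size <- attr(seg$trace, "pixel_size")
  if (is.null(frame_interval)) frame_interval <- attr(seg$trace, "frame_interval")
  if (!isTRUE(is.finite(pixel_size)) || !isTRUE(is.finite(frame_interval)))
    stop("pixel_size and frame_interval are required (trace carries no calibration)")

  tr <- seg$first_triangle
  ph <- seg$phases
  x <- seg$trace$tip_px
  out <- data.frame(length_um = NA_real_, lifetime_min = NA_real_,
                    growth_rate = NA_real_, shrink_rate = NA_real_,
                    nucleation_time_min = NA_real_, censored = tr$censored)
  if (!is.na(tr$growth)) {
    g <- ph[tr$growth, ]
    frames_in <- g$start_frame:(if (!is.na(tr$shrinkage)) ph$end_frame[tr$shrinkage] else g$end_frame)
    out$length_um <- max(x[frames_in]) * pixel_size
    ## when growth follows a baseline phase, its recorded start frame is
    ## the last baseline frame; the microtubule first appears one frame
    ## later
    nuc_frame <- if (tr$growth > 1L && ph$kind[tr$growth - 1L] == "nucleating")
      g$start_frame + 1L else g$start_frame
    ## growth ends at the peak frame: boundary intervals absorbed into
    ## the growth run would otherwise stretch the lifetime
    peak <- frames_in[which.max(x[frames_in])]
    out$lifetime_min <- (peak - nuc_frame) * frame_interval / 60
    out$growth_rate <- g$slope_px_per_frame * pixel_size * 60 / frame_interval
    out$nucleation_time_min <- (nuc_frame - mix_frame) * frame_interval / 60
    if (!is.na(tr$shrinkage))
      out$shrink_rate <- -ph$slope_px_per_frame[tr$shrinkage] * pixel_size * 60 / frame_interval
  }
  attr(out, "rescue_events") <- classify_rescue(seg, rescue_threshold_px)
  class(out) <- c("mt_dynamics", "data.frame")
  out
}

#' Classify rescue events with the 5-pixel seed rule
#'
#' Every termination of a shrinkage phase is an event: a
#' shrinkage-to-growth transition is a rescue, called a true rescue only
#' if the tip is more than \code{threshold_px} pixels from the seed at
#' the transition; a shrinkage that runs back to the seed is an event
#' with \code{is_true_rescue = FALSE}. Shrinkage still ongoing when the
#' movie ends is censored and not an event.
#'
#' @param seg a \code{\link{segment_phases}} result.
#' @param threshold_px distance-from-seed threshold in pixels.
#' @return data frame with one row per event: \code{frame},
#'   \code{position_px}, \code{rescued}, \code{is_true_rescue}.
#' @export
classify_rescue <- function(seg, threshold_px = 5L) {
  stopifnot(inherits(seg, "phase_segmentation"))
  ph <- seg$phases
  x <- seg$trace$tip_px
  rows <- list()
  for (i in which(ph$kind == "shrinkage")) {
    if (i == nrow(ph)) next                     # censored: movie ends mid-shrinkage
    f <- ph$end_frame[i]
    ## the transition frame can be shifted by one by trace smoothing;
    ## the rescue position is the trough around it
    nb <- max(1L, f - 1L):min(length(x), f + 1L)
    pos <- min(x[nb])
    rescued <- ph$kind[i + 1L] == "growth"
    rows[[length(rows) + 1L]] <- data.frame(
      frame = f, position_px = pos, rescued = rescued,
      is_true_rescue = rescued && pos > threshold_px)
  }
  if (!length(rows))
    return(data.frame(frame = integer(0), position_px = numeric(0),
                      rescued = logical(0), is_true_rescue = logical(0)))
  do.call(rbind, rows)
}

#' Rescue probability per replicate
#'
#' True rescues divided by all events, per replicate; the condition
#' estimate is the mean over replicates. Replicates with zero events are
#' excluded with a warning.
#'
#' @param events data frame with logical \code{is_true_rescue} (e.g.
#'   pooled \code{\link{classify_rescue}} rows) and optionally a
#'   \code{replicate} column.
#' @return list with \code{per_replicate} (named fractions) and
#'   \code{estimate} (their mean).
#' @examples
#' rescue_probability(data.frame(is_true_rescue = c(TRUE, TRUE, FALSE, FALSE, FALSE)))
#' @export
rescue_probability <- function(events) {
  stopifnot(is.data.frame(events), "is_true_rescue" %in% names(events))
  if (!nrow(events)) stop("no events: rescue probability is undefined")
  rep_id <- if ("replicate" %in% names(events)) events$replicate else rep(1L, nrow(events))
  frac <- tapply(events$is_true_rescue, rep_id, function(z) sum(z) / length(z))
  frac <- stats::setNames(as.numeric(frac), names(frac))
  list(per_replicate = frac, estimate = mean(frac))
}

#' Aggregate per-microtubule dynamics into a dose-response table
#'
#' Per condition (e.g. binder concentration): number of microtubules,
#' mean and SD of each dynamic parameter, and the replicate-averaged
#' rescue probability. Censored (missing) values are excluded from the
#' affected statistic.
#'
#' @param per_mt data frame with one row per microtubule: a
#'   \code{concentration} column, the \code{\link{compute_dynamics_summary}}
#'   columns, and optionally \code{replicate}.
#' @param events optional pooled event data frame with
#'   \code{concentration}, \code{replicate}, \code{is_true_rescue} for
#'   rescue probabilities.
#' @return data frame of class \code{dose_response}, one row per
#'   concentration.
#' @export
aggregate_conditions <- function(per_mt, events = NULL) {
  stopifnot(is.data.frame(per_mt), "concentration" %in% names(per_mt))
  stats_cols <- intersect(c("length_um", "lifetime_min", "growth_rate",
                            "shrink_rate", "nucleation_time_min"),
                          names(per_mt))
  concs <- sort(unique(per_mt$concentration))
  rows <- lapply(concs, function(cc) {
    sub <- per_mt[per_mt$concentration == cc, , drop = FALSE]
    row <- data.frame(concentration = cc, n = nrow(sub))
    for (s in stats_cols) {
      v <- sub[[s]]
      row[[paste0("mean_", s)]] <- mean(v, na.rm = TRUE)
      row[[paste0("sd_", s)]] <- stats::sd(v[!is.na(v)])
    }
    if (!is.null(events)) {
      ev <- events[events$concentration == cc, , drop = FALSE]
      row$rescue_probability <- if (nrow(ev)) rescue_probability(ev)$estimate else NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("dose_response", "data.frame")
  out
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("Dose-response table: %d conditions, %d microtubules total\n",
              nrow(x), sum(x$n)))
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' @export
plot.dose_response <- function(x, stat = "mean_length_um", ...) {
  graphics::plot(x$concentration, x[[stat]], type = "b", pch = 16,
                 xlab = "concentration", ylab = stat, ...)
  invisible(x)
}
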