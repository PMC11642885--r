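#' Density volume container
#'
#' A minimal 3-D density volume: numeric array plus voxel size and
#' origin. The origin is the coordinate (in Angstrom) of the center of
#' voxel \code{[1,1,1]}, so voxel \code{[i,j,k]} sits at
#' \code{origin + (c(i,j,k) - 1) * voxel_size}.
#'
#' @param data numeric 3-D array.
#' @param voxel_size voxel edge length, Angstrom.
#' @param origin 3-vector, Angstrom.
#' @return object of class \code{mt_volume}.
#' @export
mt_volume <- function(data, voxel_size, origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!is.finite(voxel_size) || voxel_size <= 0) stop("voxel_size must be > 0")
  structure(list(data = data, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "mt_volume")
}

#' @export
print.mt_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Density volume %d x %d x %d, voxel %.2f A, origin (%.1f, %.1f, %.1f) A\n",
              d[1], d[2], d[3], x$voxel_size,
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  density range [%.3g, %.3g], mean %.3g\n",
              min(x$data), max(x$data), mean(x$data)))
  invisible(x)
}

## Gaussian blob footprint (ranges and separable weights) at fractional
## voxel position p (1-based, voxel units); NULL if outside the grid
.blob_footprint <- function(d, p, sigma_vox) {
  w <- ceiling(3 * sigma_vox)
  rng <- lapply(1:3, function(i) {
    lo <- max(1L, floor(p[i]) - w); hi <- min(d[i], ceiling(p[i]) + w)
    if (lo > hi) return(integer(0))
    lo:hi
  })
  if (any(vapply(rng, length, 0L) == 0L)) return(NULL)
  g <- lapply(1:3, function(i) exp(-(rng[[i]] - p[i])^2 / (2 * sigma_vox^2)))
  list(rng = rng, blob = g[[1L]] %o% g[[2L]] %o% g[[3L]])
}

#' Synthesize a tomographic volume of a (decorated) microtubule lattice
#'
#' Renders every monomer site of the lattice as a Gaussian blob, adds
#' optional decoration blobs with an 8-nm axial repeat at the exterior of
#' chosen lateral junctions, adds Gaussian noise at the requested
#' signal-to-noise ratio and, if a missing-wedge half-angle is given,
#' zeroes the Fourier amplitudes inside the missing wedge. The filament
#' axis is the volume z axis; the tomographic beam direction is the
#' volume x axis with tilt axis y, so a \code{wedge} of 60 means tilt
#' coverage -60..60 degrees and real-space smearing along x.
#'
#' SNR is defined as \code{sd(noise-free volume) / sd(noise)}.
#'
#' @param lattice an \code{\link{mt_lattice}} (coordinates nm; converted
#'   to Angstrom here).
#' @param decorations \code{NULL}, or a data frame with columns
#'   \code{junction} (index i for junction \code{(i, i+1)}), and
#'   optionally \code{radial_offset} (nm outward from the
#'   protofilament radius; default 4), \code{sigma} (blob SD nm, default
#'   1.5) and \code{occupancy} (per-repeat binding probability, default
#'   1).
#' @param voxel_size Angstrom (>= 2).
#' @param snr signal-to-noise ratio; \code{Inf} for noise-free.
#' @param wedge missing-wedge tilt half-range in degrees (e.g. 60), or
#'   \code{NULL} for full sampling.
#' @param seed integer seed for noise and partial occupancy.
#' @param blob_sigma monomer blob SD, nm.
#' @param pad empty border around the lattice, Angstrom.
#' @return An \code{mt_volume} whose frame contains the lattice
#'   coordinates in Angstrom (site at \code{10 * c(x,y,z)}).
#' @examples
#' v <- render_lattice_volume(mt_lattice(13, 4), voxel_size = 8)
#' @export
render_lattice_volume <- function(lattice, decorations = NULL, voxel_size = 8,
                                  snr = Inf, wedge = NULL, seed = NULL,
                                  blob_sigma = 1.2, pad = 30) {
  stopifnot(inherits(lattice, "mt_lattice"))
  if (voxel_size < 2) stop("voxel_size must be >= 2 Angstrom")
  if (!is.null(seed)) set.seed(as.integer(seed))

  dec <- NULL
  if (!is.null(decorations)) {
    dec <- as.data.frame(decorations)
    if (!"junction" %in% names(dec)) stop("decorations need a 'junction' column")
    if (!"radial_offset" %in% names(dec)) dec$radial_offset <- 4.0
    if (!"sigma" %in% names(dec)) dec$sigma <- 1.5
    if (!"occupancy" %in% names(dec)) dec$occupancy <- 1.0
    if (any(!dec$junction %in% seq_len(lattice$n_pf)))
      stop("decoration junction not in the lattice")
    if (any(dec$occupancy < 0 | dec$occupancy > 1))
      stop("occupancy must be in [0, 1]")
  }

  sites_A <- as.matrix(lattice$sites[, c("x", "y", "z")]) * 10
  r_out <- max(sqrt(sites_A[, 1L]^2 + sites_A[, 2L]^2))
  if (!is.null(dec)) r_out <- max(r_out, (lattice$radius + max(dec$radial_offset)) * 10)
  half_xy <- r_out + 3 * blob_sigma * 10 + pad
  z_lo <- min(sites_A[, 3L]) - 3 * blob_sigma * 10 - pad
  z_hi <- max(sites_A[, 3L]) + 3 * blob_sigma * 10 + pad
  nx <- .good_fft_size(2L * ceiling(half_xy / voxel_size))
  nz <- .good_fft_size(ceiling((z_hi - z_lo) / voxel_size))
  origin <- c(-((nx - 1) / 2) * voxel_size, -((nx - 1) / 2) * voxel_size, z_lo)

  a <- array(0, dim = c(nx, nx, nz))
  dd <- dim(a)
  sig_vox <- blob_sigma * 10 / voxel_size
  for (i in seq_len(nrow(sites_A))) {
    p <- (sites_A[i, ] - origin) / voxel_size + 1
    f <- .blob_footprint(dd, p, sig_vox)
    if (!is.null(f))
      a[f$rng[[1L]], f$rng[[2L]], f$rng[[3L]]] <-
        a[f$rng[[1L]], f$rng[[2L]], f$rng[[3L]]] + f$blob
  }

  if (!is.null(dec)) {
    geo <- lattice$pf_geometry
    ang <- lattice$angle_profile$angle_deg
    for (q in seq_len(nrow(dec))) {
      i <- dec$junction[q]
      az <- (geo$azimuth_deg[geo$pf == i] + ang[i] / 2) * pi / 180
      rr <- (lattice$radius + dec$radial_offset[q]) * 10
      z0 <- geo$z_offset[geo$pf == i] * 10 + lattice$dimer_rise * 10 / 2
      bound <- stats::rbinom(lattice$n_repeats, 1L, dec$occupancy[q]) == 1L
      for (r in which(bound)) {
        ctr <- c(rr * cos(az), rr * sin(az),
                 z0 + (r - 1) * lattice$dimer_rise * 10)
        p <- (ctr - origin) / voxel_size + 1
        f <- .blob_footprint(dd, p, dec$sigma[q] * 10 / voxel_size)
        if (!is.null(f))
          a[f$rng[[1L]], f$rng[[2L]], f$rng[[3L]]] <-
            a[f$rng[[1L]], f$rng[[2L]], f$rng[[3L]]] + f$blob
      }
    }
  }

  if (is.finite(snr)) {
    if (snr <= 0) stop("snr must be > 0")
    a <- a + stats::rnorm(length(a), sd = stats::sd(as.numeric(a)) / snr)
  }
  vol <- mt_volume(a, voxel_size, origin)
  if (!is.null(wedge)) vol <- apply_missing_wedge(vol, wedge)
  vol
}

#' Apply a tomographic missing wedge in Fourier space
#'
#' Zeroes Fourier components outside the tilt coverage of a single-axis
#' tilt series: beam along x, tilt axis y, tilt range
#' \code{-half_angle..half_angle} degrees. A component with frequency
#' vector \code{(kx, ky, kz)} is kept iff
#' \code{atan2(|kx|, |kz|) <= half_angle}. The operation is a Fourier
#' mask, hence idempotent.
#'
#' @param vol an \code{mt_volume}.
#' @param half_angle tilt half-range, degrees, in (0, 90).
#' @return the wedge-filtered \code{mt_volume}.
#' @export
apply_missing_wedge <- function(vol, half_angle = 60) {
  stopifnot(inherits(vol, "mt_volume"))
  if (half_angle <= 0 || half_angle >= 90)
    stop("half_angle must be in (0, 90) degrees")
  d <- dim(vol$data)
  fx <- .fft_freqs(d[1L]) / (d[1L] * vol$voxel_size)
  fz <- .fft_freqs(d[3L]) / (d[3L] * vol$voxel_size)
  keep2 <- outer(abs(fx), abs(fz), function(a, b) atan2(a, b) <= half_angle * pi / 180)
  mask <- aperm(array(keep2, dim = c(d[1L], d[3L], d[2L])), c(1L, 3L, 2L))
  F <- stats::fft(vol$data)
  vol$data <- Re(stats::fft(F * mask, inverse = TRUE)) / length(F)
  vol
}

## next even 5-smooth integer >= n (fast mixed-radix FFT length)
.good_fft_size <- function(n) {
  n <- as.integer(n)
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L && n %% 2L == 0L) return(n)
    n <- n + 1L
  }
}

## integer DFT frequency indices 0, 1, ..., n/2, -(n/2-1), ..., -1
.fft_freqs <- function(n) {
  c(seq.int(0L, floor(n / 2)), seq.int(-(ceiling(n / 2) - 1L), -1L))
}

#' Interpolate a subtomogram picking grid along a filament trace
#'
#' Places subtomogram centers at fixed arc-length intervals along a
#' traced filament polyline (the 8-nm picking used for filaments in
#' subtomogram averaging), with the local polyline direction as tangent.
#'
#' @param trace matrix or data frame of polyline points, columns
#'   \code{x,y,z}, Angstrom.
#' @param spacing arc-length spacing, Angstrom (default 80 = 8 nm).
#' @return object of class \code{subtomo_grid}: data frame with center
#'   coordinates \code{x,y,z} and unit tangents \code{tx,ty,tz};
#'   attribute \code{spacing}.
#' @examples
#' g <- interpolate_filament_grid(cbind(x = seq(0, 800, 100), y = 0, z = 0))
#' nrow(g) # 11 centers on a straight 800-A trace
#' @export
interpolate_filament_grid <- function(trace, spacing = 80) {
  if (is.data.frame(trace)) trace <- as.matrix(trace[, c("x", "y", "z")])
  trace <- matrix(as.numeric(trace), ncol = 3L,
                  dimnames = list(NULL, c("x", "y", "z")))
  if (nrow(trace) < 2L) stop("a trace needs at least 2 points")
  seg <- diff(trace)
  seg_len <- sqrt(rowSums(seg^2))
  if (any(seg_len == 0)) stop("consecutive trace points must be distinct")
  if (spacing <= 0) stop("spacing must be > 0")
  s <- c(0, cumsum(seg_len))
  total <- s[length(s)]
  if (total < spacing)
    stop(sprintf("trace arc length (%.1f A) is shorter than one spacing (%.1f A)",
                 total, spacing))
  t_at <- seq(0, total, by = spacing)
  ## segment containing each arc position; exact joints use the next segment
  si <- findInterval(t_at, s, rightmost.closed = TRUE)
  si[si >= nrow(trace)] <- nrow(trace) - 1L
  frac <- (t_at - s[si]) / seg_len[si]
  ctr <- trace[si, , drop = FALSE] + seg[si, , drop = FALSE] * frac
  tang <- seg[si, , drop = FALSE] / seg_len[si]
  out <- data.frame(x = ctr[, 1L], y = ctr[, 2L], z = ctr[, 3L],
                    tx = tang[, 1L], ty = tang[, 2L], tz = tang[, 3L])
  attr(out, "spacing") <- spacing
  class(out) <- c("subtomo_grid", "data.frame")
  out
}

## polar coordinates of the xy grid of a volume about (cx, cy) in A
.polar_xy <- function(vol, cx = 0, cy = 0) {
  d <- dim(vol$data)
  xs <- vol$origin[1L] + (seq_len(d[1L]) - 1) * vol$voxel_size
  ys <- vol$origin[2L] + (seq_len(d[2L]) - 1) * vol$voxel_size
  X <- matrix(xs, d[1L], d[2L])
  Y <- matrix(ys, d[1L], d[2L], byrow = TRUE)
  list(r = sqrt((X - cx)^2 + (Y - cy)^2),
       phi = (atan2(Y - cy, X - cx) * 180 / pi) %% 360)
}

#' Classify microtubule protofilament number from a rotational spectrum
#'
#' Computes the rotational power spectrum of the density annulus at the
#' protofilament radius and picks the candidate N with the largest
#' background-normalized power at its signature angular harmonics. For a
#' helical lattice the N-fold harmonic at zero axial frequency is
#' destroyed by the missing wedge (it needs in-plane resolution along
#' the beam), but the monomer layer line at 1/(4 nm) survives a
#' +/-60 degree tilt geometry and carries harmonics
#' \code{N - n_start} and \code{N + n_start}; power is integrated
#' there.
#'
#' @param vol an \code{mt_volume}, or a list of equally-sized aligned
#'   subvolumes of one filament (they are averaged first). Filament axis
#'   along volume z.
#' @param candidates candidate protofilament numbers.
#' @param margin_min minimum difference between the best and second-best
#'   normalized scores; below it the filament is \code{unclassified}
#'   (\code{n_pf = NA}). The default sits well above the margins that
#'   pure-noise volumes produce (largest observed over hundreds of noise
#'   draws is about 3) and well below genuine lattice signals.
#' @param n_phi angular bins for the rotational profile.
#' @param n_start start number of the monomer helix (3 for the canonical
#'   12-nm/turn B-lattice); sets which angular harmonics carry the
#'   layer-line power (\code{N - n_start} and \code{N + n_start}).
#' @param period_A axial dimer repeat in Angstrom (monomer layer line at
#'   \code{2/period_A}).
#' @return list with \code{n_pf} (integer or NA), \code{scores} (named
#'   per candidate), and \code{margin}.
#' @export
classify_pf_number <- function(vol, candidates = c(13L, 14L),
                               margin_min = 4, n_phi = 64L,
                               n_start = 3L, period_A = 80) {
  if (is.list(vol) && !inherits(vol, "mt_volume")) {
    stopifnot(length(vol) >= 1L, all(vapply(vol, inherits, TRUE, "mt_volume")))
    acc <- vol[[1L]]$data
    if (length(vol) > 1L) for (i in 2L:length(vol)) acc <- acc + vol[[i]]$data
    vol <- mt_volume(acc / length(vol), vol[[1L]]$voxel_size, vol[[1L]]$origin)
  }
  stopifnot(inherits(vol, "mt_volume"))
  d <- dim(vol$data)
  if (any(d < 32L)) stop("analysis volumes must be at least 32 voxels per axis")
  candidates <- as.integer(candidates)
  if (any(candidates >= n_phi / 2)) stop("candidates beyond angular Nyquist")

  ## center: intensity-weighted centroid of the z-mean projection
  proj <- apply(vol$data, c(1L, 2L), mean)
  w <- pmax(proj - stats::median(proj), 0)
  xs <- vol$origin[1L] + (seq_len(d[1L]) - 1) * vol$voxel_size
  ys <- vol$origin[2L] + (seq_len(d[2L]) - 1) * vol$voxel_size
  sw <- sum(w)
  if (sw <= 0) return(list(n_pf = NA_integer_, scores = NULL, margin = 0))
  cx <- sum(rowSums(w) * xs) / sw
  cy <- sum(colSums(w) * ys) / sw

  pol <- .polar_xy(vol, cx, cy)
  ## protofilament radius from the radial profile of the projection
  rmax <- min(abs(c(xs[1L], xs[d[1L]] , ys[1L], ys[d[2L]]))) - vol$voxel_size
  rbin <- floor(pol$r / vol$voxel_size) + 1L
  nb <- floor(rmax / vol$voxel_size)
  ok <- rbin <= nb
  radial <- tapply(proj[ok], rbin[ok], mean)
  rads <- (as.integer(names(radial)) - 0.5) * vol$voxel_size
  sel <- rads > 3 * vol$voxel_size
  r_pf <- rads[sel][which.max(radial[sel])]

  ann <- ok & abs(pol$r - r_pf) <= 2.5 * vol$voxel_size
  idx <- which(ann)
  pbin <- pmin(floor(pol$phi[idx] / (360 / n_phi)) + 1L, n_phi)
  vm <- matrix(vol$data, d[1L] * d[2L], d[3L])
  counts <- tabulate(pbin, n_phi)
  if (any(counts == 0L))   # degenerate annulus (e.g. pure noise): no decision
    return(list(n_pf = NA_integer_, scores = NULL, margin = 0))
  A <- rowsum(vm[idx, , drop = FALSE], pbin) / counts

  ## 2D power spectrum over (angular harmonic m, axial frequency kz)
  C2 <- t(stats::mvfft(t(stats::mvfft(A))))
  P2 <- Mod(C2)^2
  ## monomer layer line: kz = 1/(dimer_rise/2); for an n_start helix the
  ## N-protofilament lattice puts its power at m = N -/+ n_start there
  k4 <- d[3L] * vol$voxel_size / (period_A / 2)
  kz_bins <- unique(pmin(pmax(round(k4) + (-1:1), 1L), d[3L] - 1L))
  kz_idx <- unique(c(kz_bins + 1L, d[3L] - kz_bins + 1L))
  P_ll <- rowSums(P2[, kz_idx, drop = FALSE])

  m_sig <- function(N) c(N - n_start, N + n_start)
  m_excl <- unique(unlist(lapply(candidates, m_sig)))
  m_bg <- setdiff(seq(6L, min(24L, n_phi / 2 - 1L)), m_excl)
  bg <- stats::median(P_ll[m_bg + 1L])
  if (bg <= 0) return(list(n_pf = NA_integer_, scores = NULL, margin = 0))
  scores <- vapply(candidates, function(N) sum(P_ll[m_sig(N) + 1L]), 0) / bg
  names(scores) <- candidates
  o <- order(scores, decreasing = TRUE)
  margin <- if (length(scores) > 1L) scores[o[1L]] - scores[o[2L]] else scores[o[1L]]
  n_pf <- if (margin >= margin_min) candidates[o[1L]] else NA_integer_
  list(n_pf = n_pf, scores = scores, margin = unname(margin))
}

#' Score 8-nm-periodic decoration at every lateral junction
#'
#' For each junction of a fitted lattice model registered to the volume,
#' samples the mean density in an external shell sector centered on the
#' junction azimuth as a function of axial position, and scores the
#' spectral power at the dimer frequency (1 / dimer rise) with Welch
#' averaging. Junction z-scores are robust (median/MAD over junctions,
#' on the log of the score), so a minority of decorated junctions cannot
#' mask themselves. Junctions with z-score at or above \code{threshold}
#' are called decorated.
#'
#' @param vol \code{mt_volume} in the same frame as the lattice (as
#'   produced by \code{\link{render_lattice_volume}}).
#' @param lattice the registered \code{\link{mt_lattice}}.
#' @param shell radial sampling shell beyond the protofilament radius,
#'   nm, as \code{c(inner, outer)}.
#' @param threshold z-score calling threshold.
#' @param periods_per_segment Welch segment length in dimer periods.
#' @return data frame of class \code{decoration_profile}: \code{pf_i},
#'   \code{pf_j}, \code{score}, \code{zscore}, \code{called}; attributes
#'   \code{threshold} and \code{period_A}.
#' @export
junction_decoration_profile <- function(vol, lattice, shell = c(2, 6),
                                        threshold = 3, periods_per_segment = 2L) {
  stopifnot(inherits(vol, "mt_volume"), inherits(lattice, "mt_lattice"))
  d <- dim(vol$data)
  if (any(d < 32L)) stop("analysis volumes must be at least 32 voxels per axis")
  sites_A <- as.matrix(lattice$sites[, c("x", "y", "z")]) * 10
  lo <- vol$origin - vol$voxel_size / 2
  hi <- vol$origin + (d - 1L) * vol$voxel_size + vol$voxel_size / 2
  if (any(t(sites_A) < lo) || any(t(sites_A) > hi))
    stop("lattice sites fall outside the volume: model/volume frame mismatch")

  pol <- .polar_xy(vol, 0, 0)
  r_in <- (lattice$radius + shell[1L]) * 10
  r_out <- (lattice$radius + shell[2L]) * 10
  period_vox <- lattice$dimer_rise * 10 / vol$voxel_size
  seg_len <- round(periods_per_segment * period_vox)
  if (seg_len < 4L || seg_len > d[3L])
    stop("volume too short along z for the requested Welch segments")
  starts <- seq(1L, d[3L] - seg_len + 1L, by = max(1L, floor(seg_len / 2)))
  vm <- matrix(vol$data, d[1L] * d[2L], d[3L])

  geo <- lattice$pf_geometry
  ang <- lattice$angle_profile$angle_deg
  n <- lattice$n_pf
  ## frequency bins per Welch segment: the dimer target plus background
  ## bins used to build the null (skipping the low-frequency trend bins
  ## and the monomer harmonic at twice the target)
  target_bin <- periods_per_segment + 1L
  bg_bins <- setdiff(seq(target_bin + 1L, min(seg_len %/% 2, target_bin + 5L)),
                     2L * periods_per_segment + 1L)
  scores <- numeric(n)
  bg_scores <- matrix(0, n, length(bg_bins))
  for (i in seq_len(n)) {
    az_c <- (geo$azimuth_deg[geo$pf == i] + ang[i] / 2) %% 360
    dphi <- abs(((pol$phi - az_c + 180) %% 360) - 180)
    mask <- pol$r >= r_in & pol$r <= r_out & dphi <= ang[i] / 2
    idx <- which(mask)
    if (!length(idx)) stop("empty shell sector; shrink the shell or enlarge the volume")
    p <- colMeans(vm[idx, , drop = FALSE])
    pw <- vapply(starts, function(s0) {
      seg <- p[s0:(s0 + seg_len - 1L)]
      tt <- seq_along(seg)
      seg <- stats::residuals(stats::lm.fit(cbind(1, tt), seg))
      Mod(stats::fft(seg)[c(target_bin, bg_bins)])^2
    }, numeric(1L + length(bg_bins)))
    pw <- matrix(pw, nrow = 1L + length(bg_bins))
    scores[i] <- mean(pw[1L, ])
    bg_scores[i, ] <- rowMeans(pw[-1L, , drop = FALSE])
  }
  ## null from the pooled background-frequency scores of all junctions:
  ## many more draws than the 13 junction scores alone, so the spread
  ## estimate is stable and a decorated minority cannot mask itself
  ls <- log(pmax(scores, .Machine$double.xmin))
  lbg <- log(pmax(as.numeric(bg_scores), .Machine$double.xmin))
  z <- (ls - stats::median(lbg)) / stats::mad(lbg)
  out <- data.frame(pf_i = seq_len(n), pf_j = c(2:n, 1L),
                    score = scores, zscore = z, called = z >= threshold)
  attr(out, "threshold") <- threshold
  attr(out, "period_A") <- lattice$dimer_rise * 10
  class(out) <- c("decoration_profile", "data.frame")
  out
}

#' @export
print.decoration_profile <- function(x, ...) {
  cat(sprintf("Junction decoration profile: %d junctions, %d called at z >= %.1f\n",
              nrow(x), sum(x$called), attr(x, "threshold")))
  if (any(x$called))
    cat("  called:", paste(sprintf("(%d,%d)", x$pf_i[x$called], x$pf_j[x$called]),
                           collapse = ", "), "\n")
  print.data.frame(x, digits = 3, ...)
  invisible(x)
}

#' Call a seam binder from a junction decoration profile
#'
#' A seam binder decorates exactly one lateral junction (the seam). A
#' single called junction is a unique seam call; several called
#' junctions are reported as multiple candidate seams (e.g. stabilized
#' microtubules with multiple seams); none leaves the call empty.
#'
#' @param profile a \code{\link{junction_decoration_profile}} result.
#' @return list with \code{junction} (PF pair or NULL), \code{unique}
#'   (logical), and \code{multi_site_junctions} (list of PF pairs; empty
#'   unless several junctions are called).
#' @export
call_seam_binder <- function(profile) {
  stopifnot(inherits(profile, "decoration_profile"))
  hit <- which(profile$called)
  if (length(hit) == 0L)
    return(list(junction = NULL, unique = FALSE, multi_site_junctions = list()))
  if (length(hit) == 1L)
    return(list(junction = c(profile$pf_i[hit], profile$pf_j[hit]),
                unique = TRUE, multi_site_junctions = list()))
  list(junction = NULL, unique = FALSE,
       multi_site_junctions = lapply(hit, function(h) c(profile$pf_i[h], profile$pf_j[h])))
}
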