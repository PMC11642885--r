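#' Inter-protofilament angle profile
#'
#' Constructs an angle profile around a microtubule cross-section: one
#' central angle per lateral junction \code{(i, i+1)} (the last junction
#' wraps, \code{(n_pf, 1)}). Angles are in degrees and must close the
#' circle (sum to 360).
#'
#' @param angles numeric vector of per-junction angles in degrees, ordered
#'   by protofilament index; \code{angles[i]} is the angle of junction
#'   \code{(i, i+1)}.
#' @param sd optional per-junction standard deviation (degrees), e.g. the
#'   spread over axial repeats when the profile was measured.
#' @param tol maximum allowed deviation of \code{sum(angles)} from 360.
#' @return An object of class \code{pf_angle_profile}: a data frame with
#'   columns \code{pf_i}, \code{pf_j}, \code{angle_deg} and (if given)
#'   \code{sd_deg}.
#' @examples
#' pf_angle_profile(rep(360 / 13, 13))
#' @export
pf_angle_profile <- function(angles, sd = NULL, tol = 0.01) {
  angles <- as.numeric(angles)
  n <- length(angles)
  if (n < 8L) stop("an angle profile needs at least 8 junctions")
  if (any(!is.finite(angles)) || any(angles <= 0))
    stop("all junction angles must be finite and > 0")
  if (abs(sum(angles) - 360) > tol)
    stop(sprintf("angle profile must sum to 360 degrees (got %.6f)", sum(angles)))
  prof <- data.frame(
    pf_i = seq_len(n),
    pf_j = c(seq_len(n)[-1L], 1L),
    angle_deg = angles
  )
  if (!is.null(sd)) {
    stopifnot(length(sd) == n)
    prof$sd_deg <- as.numeric(sd)
  }
  class(prof) <- c("pf_angle_profile", "data.frame")
  prof
}

#' @export
print.pf_angle_profile <- function(x, ...) {
  cat(sprintf("Inter-PF angle profile: %d junctions, sum %.4f deg\n",
              nrow(x), sum(x$angle_deg)))
  cat(sprintf("  range %.3f - %.3f deg, mean %.3f deg\n",
              min(x$angle_deg), max(x$angle_deg), mean(x$angle_deg)))
  invisible(x)
}

#' Parametric microtubule B-lattice with ground-truth seam
#'
#' Builds an N-protofilament microtubule lattice as point monomers
#' (alpha/beta tubulin, 4 nm apart within an 8-nm dimer) on a helical
#' lattice. With the default three-start geometry
#' (\code{start_stagger = 1.5 * dimer_rise}) the accumulated stagger
#' across the closing junction leaves a half-dimer mismatch, making that
#' junction the unique heterotypic seam, as in a canonical B-lattice.
#'
#' Protofilament numbering is user-anchored: \code{seed_pf} sets which
#' physically built protofilament receives label 1, so the ground-truth
#' seam can land on any labelled junction. With the default
#' \code{seed_pf = 1} the seam is junction \code{(n_pf, 1)}, matching the
#' convention where a seam binder contacts alpha-tubulin of PF 1 and
#' beta-tubulin of PF N.
#'
#' @param n_pf number of protofilaments (>= 8).
#' @param n_repeats number of axial dimer repeats (>= 3).
#' @param radius protofilament-center radius, nm.
#' @param dimer_rise axial dimer repeat, nm (8.0 for tubulin).
#' @param start_stagger total axial rise accumulated over one full turn,
#'   nm; 12.0 (= 1.5 dimers) gives the canonical single seam, an integer
#'   multiple of \code{dimer_rise} gives a seamless (A-lattice-like) tube.
#' @param angle_profile optional \code{\link{pf_angle_profile}} giving a
#'   non-uniform azimuthal spacing; default is uniform \code{360/n_pf}.
#'   Indexed by protofilament label.
#' @param seed_pf protofilament numbering anchor in \code{1..n_pf}.
#' @return An object of class \code{mt_lattice}: list with \code{sites}
#'   (data frame \code{pf}, \code{repeat_index}, \code{chain},
#'   \code{x,y,z} in nm), \code{n_pf}, \code{radius}, \code{dimer_rise},
#'   \code{start_stagger}, \code{angle_profile}, \code{pf_geometry}
#'   (per-label azimuth and axial offset) and \code{seam_junction}
#'   (labelled PF pair, or NULL when the closing mismatch is zero).
#' @examples
#' lat <- mt_lattice(n_pf = 13, n_repeats = 4)
#' lat$seam_junction
#' @export
mt_lattice <- function(n_pf = 13L, n_repeats = 6L, radius = 11.0,
                       dimer_rise = 8.0, start_stagger = 12.0,
                       angle_profile = NULL, seed_pf = 1L) {
  n_pf <- as.integer(n_pf)
  n_repeats <- as.integer(n_repeats)
  if (is.na(n_pf) || n_pf < 8L) stop("n_pf must be an integer >= 8")
  if (is.na(n_repeats) || n_repeats < 3L) stop("n_repeats must be >= 3")
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0")
  if (!is.finite(dimer_rise) || dimer_rise <= 0) stop("dimer_rise must be > 0")
  if (!is.finite(start_stagger) || start_stagger < 0)
    stop("start_stagger must be >= 0")
  seed_pf <- as.integer(seed_pf)
  if (is.na(seed_pf) || seed_pf < 1L || seed_pf > n_pf)
    stop("seed_pf must be in 1..n_pf")

  if (is.null(angle_profile)) {
    angle_profile <- pf_angle_profile(rep(360 / n_pf, n_pf))
  } else {
    if (!inherits(angle_profile, "pf_angle_profile"))
      angle_profile <- pf_angle_profile(angle_profile)
    if (nrow(angle_profile) != n_pf)
      stop("angle_profile must have one junction per protofilament")
  }

  ## physical PF k = 1..n built around the circle; label assigned so that
  ## physical PF `seed_pf` carries label 1
  label_of <- function(k) ((k - seed_pf) %% n_pf) + 1L
  k_of_label <- function(l) ((l - 1L + seed_pf - 1L) %% n_pf) + 1L

  ## azimuth of the PF carrying label l follows the profile in label space;
  ## physical placement rotates labels around the circle
  ang <- angle_profile$angle_deg
  az_label <- c(0, cumsum(ang))[seq_len(n_pf)]           # label l at az_label[l]
  az_phys <- az_label[label_of(seq_len(n_pf))]           # physical k
  ## axial helix offset proportional to azimuth travelled from physical PF 1
  az0 <- az_phys - az_phys[1L]
  az0 <- az0 %% 360
  z_off <- start_stagger * az0 / 360

  rep_idx <- rep(seq_len(n_repeats) - 1L, each = 2L)
  chain <- rep(c("alpha", "beta"), times = n_repeats)
  dz <- rep_idx * dimer_rise + ifelse(chain == "beta", dimer_rise / 2, 0)

  sites <- do.call(rbind, lapply(seq_len(n_pf), function(k) {
    th <- az_phys[k] * pi / 180
    data.frame(
      pf = label_of(k),
      repeat_index = rep_idx,
      chain = chain,
      x = radius * cos(th),
      y = radius * sin(th),
      z = z_off[k] + dz,
      stringsAsFactors = FALSE
    )
  }))
  sites <- sites[order(sites$pf, sites$repeat_index, sites$chain), ]
  rownames(sites) <- NULL

  mismatch <- start_stagger %% dimer_rise
  seam <- NULL
  if (min(mismatch, dimer_rise - mismatch) > 1e-9) {
    ## closing junction between physical PF n_pf and PF 1 is heterotypic
    seam <- c(label_of(n_pf), label_of(1L))
  }

  pf_geometry <- data.frame(
    pf = label_of(seq_len(n_pf)),
    azimuth_deg = az_phys,
    z_offset = z_off
  )
  pf_geometry <- pf_geometry[order(pf_geometry$pf), ]
  rownames(pf_geometry) <- NULL

  structure(list(
    sites = sites,
    n_pf = n_pf,
    n_repeats = n_repeats,
    radius = radius,
    dimer_rise = dimer_rise,
    start_stagger = start_stagger,
    angle_profile = angle_profile,
    pf_geometry = pf_geometry,
    seam_junction = seam,
    closing_mismatch = mismatch
  ), class = "mt_lattice")
}

#' @export
print.mt_lattice <- function(x, ...) {
  cat(sprintf("Microtubule lattice: %d PFs x %d dimer repeats (%d monomer sites)\n",
              x$n_pf, x$n_repeats, nrow(x$sites)))
  cat(sprintf("  radius %.2f nm, dimer rise %.1f nm, start stagger %.1f nm\n",
              x$radius, x$dimer_rise, x$start_stagger))
  if (is.null(x$seam_junction)) {
    cat("  seamless (integer-dimer helix closure)\n")
  } else {
    cat(sprintf("  seam at junction (%d, %d), closing mismatch %.2f nm\n",
                x$seam_junction[1], x$seam_junction[2], x$closing_mismatch))
  }
  invisible(x)
}

#' Extract the monomer site table from a lattice or pass one through
#' @param x an \code{mt_lattice} or a site data frame with columns
#'   \code{x,y,z} (nm) and optionally \code{pf}, \code{repeat_index},
#'   \code{chain}.
#' @return site data frame
#' @export
lattice_sites <- function(x) {
  if (inherits(x, "mt_lattice")) return(x$sites)
  if (is.data.frame(x)) {
    if (!all(c("x", "y", "z") %in% names(x)))
      stop("site table needs x, y, z columns")
    return(x)
  }
  stop("expected an mt_lattice or a site data frame")
}
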