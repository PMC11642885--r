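#' Fit the filament axis of a site cloud
#'
#' When protofilament labels are present, each protofilament is a
#' straight line parallel to the lattice axis; the axis direction is the
#' sign-aligned average of the per-protofilament principal directions.
#' (Plain PCA of the whole cloud is biased for helical lattices: the
#' axial start offsets correlate with azimuth and tilt the principal
#' axis.) For unlabelled clouds the direction is refined from the PCA
#' initialisation by minimising the variance of the projected radius,
#' i.e. a cylinder fit. The origin is the centroid in both cases.
#'
#' @param x an \code{mt_lattice} or site data frame (nm).
#' @return An object of class \code{filament_axis}: list with
#'   \code{origin} (3-vector, nm) and \code{direction} (unit 3-vector).
#' @export
fit_filament_axis <- function(x) {
  sites <- lattice_sites(x)
  labelled <- all(c("pf", "repeat_index") %in% names(sites))
  if (labelled) {
    if (length(unique(sites$pf)) < 3L || length(unique(sites$repeat_index)) < 3L)
      stop("axis fitting needs at least 3 protofilaments x 3 repeats")
  }
  xyz <- as.matrix(sites[, c("x", "y", "z")])
  if (nrow(xyz) < 4L) stop("too few sites to fit an axis")
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2L, ctr))
  if (sv$d[3L] < 1e-8 * sv$d[1L])
    stop("degenerate (coplanar) site cloud: cannot define a cross-sectional plane")
  dir0 <- sv$v[, 1L]
  if (labelled) {
    dirs <- t(vapply(unique(sites$pf), function(p) {
      pxyz <- xyz[sites$pf == p, , drop = FALSE]
      d <- svd(sweep(pxyz, 2L, colMeans(pxyz)))$v[, 1L]
      if (sum(d * dir0) < 0) d <- -d
      d
    }, numeric(3L)))
    dir <- colMeans(dirs)
  } else {
    dir <- .refine_cylinder_axis(xyz, ctr, dir0)
  }
  dir <- dir / sqrt(sum(dir^2))
  dom <- which.max(abs(dir))
  if (dir[dom] < 0) dir <- -dir
  structure(list(origin = ctr, direction = dir),
            class = "filament_axis")
}

## refine an axis direction so the projected points are maximally
## circular: minimise the variance of the in-plane radius about a
## fitted circle center
.refine_cylinder_axis <- function(xyz, ctr, dir0) {
  rel <- sweep(xyz, 2L, ctr)
  obj <- function(par) {
    d <- dir0 + .plane_basis(dir0) %*% par
    d <- d / sqrt(sum(d^2))
    B <- .plane_basis(as.numeric(d))
    uv <- rel %*% B
    cc <- .fit_circle_center(uv[, 1L], uv[, 2L])
    r <- sqrt((uv[, 1L] - cc[1L])^2 + (uv[, 2L] - cc[2L])^2)
    stats::var(r)
  }
  fit <- stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 500))
  d <- dir0 + .plane_basis(dir0) %*% fit$par
  as.numeric(d / sqrt(sum(d^2)))
}

#' @export
print.filament_axis <- function(x, ...) {
  cat(sprintf("Filament axis: origin (%.2f, %.2f, %.2f) nm, direction (%.4f, %.4f, %.4f)\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

## orthonormal in-plane basis perpendicular to a unit direction
.plane_basis <- function(direction) {
  ref <- if (abs(direction[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * direction) * direction
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(direction[2L] * e1[3L] - direction[3L] * e1[2L],
          direction[3L] * e1[1L] - direction[1L] * e1[3L],
          direction[1L] * e1[2L] - direction[2L] * e1[1L])
  cbind(e1, e2)
}

## algebraic (Kasa) least-squares circle center for in-plane points
.fit_circle_center <- function(u, v) {
  A <- cbind(2 * u, 2 * v, 1)
  b <- u^2 + v^2
  sol <- qr.solve(A, b)
  c(sol[1L], sol[2L])
}

## dimer midpoints per (pf, repeat) from a site table
.dimer_midpoints <- function(sites) {
  key <- interaction(sites$pf, sites$repeat_index, drop = TRUE)
  mx <- tapply(sites$x, key, mean)
  my <- tapply(sites$y, key, mean)
  mz <- tapply(sites$z, key, mean)
  ks <- strsplit(names(mx), ".", fixed = TRUE)
  data.frame(
    pf = as.integer(vapply(ks, `[`, "", 1L)),
    repeat_index = as.integer(vapply(ks, `[`, "", 2L)),
    x = as.numeric(mx), y = as.numeric(my), z = as.numeric(mz)
  )
}

#' Measure the inter-protofilament angle profile of a labelled lattice
#'
#' For every axial repeat, dimer midpoints are projected onto the plane
#' perpendicular to the filament axis, a least-squares circle center is
#' fitted to the projected protofilament positions, and the central angle
#' between azimuthally adjacent protofilaments \code{(i, i+1)} is taken.
#' The returned profile is the per-junction mean over repeats, with its
#' standard deviation. Central angles are closed by construction: they
#' always sum to 360 degrees.
#'
#' @param x lattice or site data frame with \code{pf} and
#'   \code{repeat_index} labels.
#' @param axis optional \code{\link{fit_filament_axis}} result; fitted
#'   from the sites when missing.
#' @return A \code{\link{pf_angle_profile}} with per-junction
#'   \code{sd_deg}.
#' @examples
#' prof <- compute_inter_pf_angles(mt_lattice(13, 4))
#' range(prof$angle_deg) # 360/13 everywhere
#' @export
compute_inter_pf_angles <- function(x, axis = NULL) {
  sites <- lattice_sites(x)
  if (!all(c("pf", "repeat_index") %in% names(sites)))
    stop("sites must carry pf and repeat_index labels")
  if (is.null(axis)) axis <- fit_filament_axis(sites)
  mid <- .dimer_midpoints(sites)
  pfs <- sort(unique(mid$pf))
  n <- length(pfs)
  if (n < 8L) stop("need at least 8 protofilaments")

  B <- .plane_basis(axis$direction)
  rel <- sweep(as.matrix(mid[, c("x", "y", "z")]), 2L, axis$origin)
  uv <- rel %*% B

  reps <- sort(unique(mid$repeat_index))
  per_rep <- list()
  for (r in reps) {
    sel <- mid$repeat_index == r
    if (!setequal(mid$pf[sel], pfs)) {
      warning(sprintf("repeat %d is missing protofilaments; excluded", r))
      next
    }
    ord <- match(pfs, mid$pf[sel])
    u <- uv[sel, 1L][ord]
    v <- uv[sel, 2L][ord]
    ctr <- .fit_circle_center(u, v)
    th <- atan2(v - ctr[2L], u - ctr[1L]) * 180 / pi
    d <- (th[c(2:n, 1L)] - th) %% 360
    tot <- sum(d)
    if (abs(tot - 360) > 1) {
      ## protofilament labels run the other way around the circle
      d <- (360 - d) %% 360
      if (abs(sum(d) - 360) > 1)
        stop("projected protofilaments are not in cyclic order around the axis")
    }
    per_rep[[length(per_rep) + 1L]] <- d
  }
  if (length(per_rep) < 3L) stop("fewer than 3 usable axial repeats")
  M <- do.call(rbind, per_rep)
  pf_angle_profile(colMeans(M), sd = apply(M, 2L, stats::sd))
}

#' Classify lateral junctions as homotypic or heterotypic (seam search)
#'
#' For each azimuthally adjacent protofilament pair, every monomer's
#' nearest lateral neighbour on the partner protofilament (within an
#' axial window) is found. A junction where the nearest neighbour of an
#' alpha monomer is predominantly beta (and vice versa) is heterotypic --
#' a seam of the B-lattice. Monomers whose nearest same-chain and
#' cross-chain candidates are closer than \code{margin} apart are treated
#' as indeterminate votes.
#'
#' @param x lattice or labelled site data frame (needs \code{pf} and
#'   \code{chain}).
#' @param axis optional precomputed \code{filament_axis}.
#' @param axial_window lateral-neighbour search window along the axis, nm.
#' @param margin minimum distance margin (nm) by which the winning
#'   pairing must beat the alternative.
#' @return Data frame of class \code{junction_table}: \code{pf_i},
#'   \code{pf_j}, \code{lateral_pairing} (\code{homotypic},
#'   \code{heterotypic} or \code{indeterminate}), \code{axial_offset}
#'   (signed modular stagger, nm) and \code{is_seam}.
#' @examples
#' classify_junctions(mt_lattice(13, 4))
#' @export
classify_junctions <- function(x, axis = NULL, axial_window = 6.0, margin = 1.0) {
  sites <- lattice_sites(x)
  if (!all(c("pf", "chain") %in% names(sites)))
    stop("sites must carry pf and chain labels")
  if (is.null(axis)) axis <- fit_filament_axis(sites)
  dimer_rise <- if (inherits(x, "mt_lattice")) x$dimer_rise else 8.0

  B <- .plane_basis(axis$direction)
  rel <- sweep(as.matrix(sites[, c("x", "y", "z")]), 2L, axis$origin)
  uv <- rel %*% B
  ax <- as.numeric(rel %*% axis$direction)

  ## azimuthal order of protofilaments
  pfs <- sort(unique(sites$pf))
  n <- length(pfs)
  az <- vapply(pfs, function(p) {
    sel <- sites$pf == p
    atan2(mean(uv[sel, 2L]), mean(uv[sel, 1L]))
  }, 0)
  ord <- pfs[order(az)]
  ## orient traversal so junction pairs follow increasing labels
  steps <- (diff(match(ord, pfs)) %% n)
  if (sum(steps == n - 1L) > sum(steps == 1L)) ord <- rev(ord)

  res <- lapply(seq_len(n), function(k) {
    pi_ <- ord[k]
    pj_ <- ord[if (k == n) 1L else k + 1L]
    si <- which(sites$pf == pi_)
    sj <- which(sites$pf == pj_)
    votes <- integer(0)       # 1 homo, -1 hetero, 0 indeterminate
    offs <- numeric(0)
    for (m in si) {
      cand <- sj[abs(ax[sj] - ax[m]) <= axial_window]
      if (!length(cand)) next
      ## the in-plane separation is common to all candidates on the
      ## partner protofilament; the pairing is decided by the axial
      ## mismatch of the nearest same-chain vs cross-chain candidate
      dax <- abs(ax[cand] - ax[m])
      same <- sites$chain[cand] == sites$chain[m]
      d_same <- if (any(same)) min(dax[same]) else Inf
      d_cross <- if (any(!same)) min(dax[!same]) else Inf
      v <- if (abs(d_same - d_cross) < margin) 0L else if (d_same < d_cross) 1L else -1L
      votes <- c(votes, v)
      nb <- cand[which.min(dax)]
      delta <- (ax[nb] - ax[m]) %% dimer_rise
      if (delta > dimer_rise / 2) delta <- delta - dimer_rise
      offs <- c(offs, delta)
    }
    n_homo <- sum(votes == 1L); n_het <- sum(votes == -1L)
    pairing <- if (!length(votes) || n_homo == n_het) "indeterminate"
               else if (n_homo > n_het) "homotypic" else "heterotypic"
    data.frame(pf_i = pi_, pf_j = pj_, lateral_pairing = pairing,
               axial_offset = if (length(offs)) stats::median(offs) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$is_seam <- out$lateral_pairing == "heterotypic"
  out <- out[order(out$pf_i), ]
  rownames(out) <- NULL
  class(out) <- c("junction_table", "data.frame")
  out
}

#' @export
print.junction_table <- function(x, ...) {
  n_seam <- sum(x$is_seam)
  cat(sprintf("Junction classification: %d junctions, %d heterotypic (seam)\n",
              nrow(x), n_seam))
  if (n_seam > 0)
    cat("  seam junction(s):",
        paste(sprintf("(%d,%d)", x$pf_i[x$is_seam], x$pf_j[x$is_seam]),
              collapse = ", "), "\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Assign protofilament labels to unlabelled dimer positions
#'
#' Points are projected onto the plane perpendicular to the axis and
#' clustered by azimuth; the cluster count is returned as the
#' protofilament-number estimate. Cluster boundaries are the large
#' circular gaps in the sorted azimuths (largest relative jump in the
#' sorted gap sequence). Stability is checked by re-counting in three
#' axial slabs; disagreement raises an error listing the candidate
#' counts.
#'
#' @param points matrix or data frame of dimer positions (columns
#'   \code{x,y,z}, nm).
#' @param axis optional \code{filament_axis}; fitted from the points when
#'   missing.
#' @param min_pf,max_pf admissible protofilament-number range.
#' @return list with \code{labels} (integer per point, numbered in
#'   azimuthal order), \code{n_pf}, and \code{azimuth_deg} per cluster.
#' @export
assign_protofilaments <- function(points, axis = NULL, min_pf = 8L, max_pf = 20L) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y", "z")])
  if (nrow(points) < 3L * min_pf) stop("too few points to cluster")
  if (is.null(axis)) {
    ctr <- colMeans(points)
    sv <- svd(sweep(points, 2L, ctr))
    dir <- .refine_cylinder_axis(points, ctr, sv$v[, 1L])
    axis <- structure(list(origin = ctr, direction = dir),
                      class = "filament_axis")
  }
  B <- .plane_basis(axis$direction)
  rel <- sweep(points, 2L, axis$origin)
  uv <- rel %*% B
  ax <- as.numeric(rel %*% axis$direction)
  phi <- (atan2(uv[, 2L], uv[, 1L]) * 180 / pi) %% 360

  count_clusters <- function(phi) {
    sp <- sort(phi)
    g <- diff(c(sp, sp[1L] + 360))
    gs <- sort(g, decreasing = TRUE)
    kmax <- min(max_pf, length(gs) - 1L)
    if (kmax < min_pf) return(NA_integer_)
    ratio <- gs[min_pf:kmax] / pmax(gs[min_pf:kmax + 1L], 1e-9)
    (min_pf:kmax)[which.max(ratio)]
  }

  n_all <- count_clusters(phi)
  slab <- cut(ax, breaks = stats::quantile(ax, c(0, 1/3, 2/3, 1)),
              include.lowest = TRUE, labels = FALSE)
  n_slab <- vapply(1:3, function(s) count_clusters(phi[slab == s]), 0L)
  cands <- unique(c(n_all, n_slab))
  if (length(cands) != 1L)
    stop(sprintf("unstable protofilament count between axial slabs (candidates: %s)",
                 paste(sort(cands), collapse = ", ")))
  n <- n_all

  ## boundaries = the n largest circular gaps
  o <- order(phi)
  sp <- phi[o]
  g <- diff(c(sp, sp[1L] + 360))
  bnd <- sort(order(g, decreasing = TRUE)[seq_len(n)])
  ## cluster of sorted point i = number of boundaries passed before it;
  ## a segment wrapping past the last sorted point rejoins cluster 1
  lab_sorted <- vapply(seq_along(sp), function(i) sum(bnd < i), 0L) + 1L
  lab_sorted[lab_sorted > n] <- 1L
  labels <- integer(length(phi))
  labels[o] <- lab_sorted
  cl_az <- vapply(seq_len(n), function(cli) {
    p <- phi[labels == cli]
    (atan2(mean(sin(p * pi / 180)), mean(cos(p * pi / 180))) * 180 / pi) %% 360
  }, 0)
  ## renumber clusters in azimuthal order
  rk <- rank(cl_az, ties.method = "first")
  labels <- rk[labels]
  list(labels = as.integer(labels), n_pf = n,
       azimuth_deg = sort(cl_az))
}
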