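## naive separable DFT (explicit exponential matrices, no fft) used as
## the independent oracle for the wedge mask
naive_dft3 <- function(a, inverse = FALSE) {
  d <- dim(a)
  sgn <- if (inverse) 2i else -2i
  dft1 <- function(n) {
    k <- 0:(n - 1)
    exp(sgn * pi * outer(k, k) / n)
  }
  Ms <- lapply(d, dft1)
  out <- array(as.complex(a), d)
  ## apply along each dimension
  m <- matrix(out, d[1], d[2] * d[3]); out <- array(Ms[[1]] %*% m, d)
  out <- aperm(out, c(2, 1, 3))
  m <- matrix(out, d[2], d[1] * d[3]); out <- array(Ms[[2]] %*% m, c(d[2], d[1], d[3]))
  out <- aperm(out, c(2, 1, 3))
  out <- aperm(out, c(3, 2, 1))
  m <- matrix(out, d[3], d[2] * d[1]); out <- array(Ms[[3]] %*% m, c(d[3], d[2], d[1]))
  aperm(out, c(3, 2, 1))
}

test_that("missing wedge equals direct Fourier masking and is idempotent", {
  set.seed(3)
  a <- array(rnorm(12 * 12 * 12), c(12, 12, 12))
  vol <- mt_volume(a, 8)
  w <- apply_missing_wedge(vol, 60)

  ## oracle: naive DFT, same mask, naive inverse
  freqs <- function(n) c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / (n * 8)
  fx <- freqs(12); fz <- freqs(12)
  keep <- outer(abs(fx), abs(fz), function(p, q) atan2(p, q) <= 60 * pi / 180)
  Fa <- naive_dft3(a)
  for (j in 1:12) Fa[, j, ] <- Fa[, j, ] * keep
  ref <- Re(naive_dft3(Fa, inverse = TRUE)) / length(Fa)
  expect_equal(w$data, ref, tolerance = 1e-8)

  ## real-space mass is conserved (DC component inside the kept region)
  expect_equal(sum(w$data), sum(ref), tolerance = 0.01 * max(1, abs(sum(ref))))

  ## idempotent
  w2 <- apply_missing_wedge(w, 60)
  expect_equal(w2$data, w$data, tolerance = 1e-10)
})

test_that("rendering is deterministic and places decorations at the junction", {
  lat <- mt_lattice(13, 6)
  v1 <- render_lattice_volume(lat, voxel_size = 8, snr = 2, wedge = 60, seed = 42)
  v2 <- render_lattice_volume(lat, voxel_size = 8, snr = 2, wedge = 60, seed = 42)
  expect_identical(v1$data, v2$data)

  ## noise-free, unwedged: brightest external voxel sits in the
  ## decorated junction's sector
  vd <- render_lattice_volume(lat, decorations = data.frame(junction = 13),
                              voxel_size = 8)
  d <- dim(vd$data)
  xs <- vd$origin[1] + (seq_len(d[1]) - 1) * vd$voxel_size
  ys <- vd$origin[2] + (seq_len(d[2]) - 1) * vd$voxel_size
  X <- matrix(xs, d[1], d[2]); Y <- matrix(ys, d[1], d[2], byrow = TRUE)
  R <- sqrt(X^2 + Y^2)
  ext <- R > (lat$radius + 2) * 10
  shell <- array(ext, d) * vd$data
  pk <- which(shell == max(shell), arr.ind = TRUE)[1, ]
  az <- (atan2(ys[pk[2]], xs[pk[1]]) * 180 / pi) %% 360
  geo <- lat$pf_geometry
  want <- (geo$azimuth_deg[geo$pf == 13] + lat$angle_profile$angle_deg[13] / 2) %% 360
  expect_lt(abs(((az - want + 180) %% 360) - 180), lat$angle_profile$angle_deg[13])

  expect_error(render_lattice_volume(lat, decorations = data.frame(junction = 14)),
               "junction")
  expect_error(render_lattice_volume(lat, voxel_size = 1), "voxel_size")
})

test_that("filament grids are spaced by arc length", {
  ## straight 800-A trace: 11 centers, gaps exactly 80 A
  g <- interpolate_filament_grid(cbind(x = seq(0, 800, by = 100), y = 0, z = 0))
  expect_equal(nrow(g), 11L)
  expect_equal(diff(g$x), rep(80, 10))

  ## 0.8-um trace gives about 100 picks
  g2 <- interpolate_filament_grid(cbind(x = seq(0, 8000, by = 250), y = 0, z = 0))
  expect_equal(nrow(g2), 101L)

  ## right-angle polyline: gaps are 80 A along arc length and tangents flip
  bend <- rbind(c(0, 0, 0), c(400, 0, 0), c(400, 400, 0))
  g3 <- interpolate_filament_grid(bend)
  arc <- function(p) {
    ifelse(p[, 1] < 400 | (p[, 1] == 400 & p[, 2] == 0), p[, 1], 400 + p[, 2])
  }
  expect_equal(diff(arc(as.matrix(g3[, 1:3]))), rep(80, nrow(g3) - 1))
  expect_equal(g3$tx[1], 1); expect_equal(g3$ty[nrow(g3)], 1)

  ## reparameterization invariance: densified collinear points
  dense <- cbind(x = seq(0, 800, by = 10), y = 0, z = 0)
  g4 <- interpolate_filament_grid(dense)
  expect_equal(as.matrix(g4[, 1:3]), as.matrix(g[, 1:3]), tolerance = 0.1)

  expect_error(interpolate_filament_grid(rbind(c(0, 0, 0), c(40, 0, 0))), "arc length")
  expect_error(interpolate_filament_grid(rbind(c(0, 0, 0), c(0, 0, 0), c(90, 0, 0))),
               "distinct")
})

test_that("protofilament number is read from the rotational spectrum", {
  lat13 <- mt_lattice(13, 12)
  lat14 <- mt_lattice(14, 12)
  ## clean volumes classify exactly
  expect_equal(classify_pf_number(render_lattice_volume(lat13, voxel_size = 8))$n_pf, 13L)
  expect_equal(classify_pf_number(render_lattice_volume(lat14, voxel_size = 8))$n_pf, 14L)

  ## wedge-filtered noisy volumes still classify
  r <- classify_pf_number(render_lattice_volume(lat13, voxel_size = 8, snr = 0.5,
                                                wedge = 60, seed = 8))
  expect_equal(r$n_pf, 13L)
  expect_gt(r$margin, 4)

  ## averaging a list of aligned subvolumes works
  vols <- lapply(1:3, function(s)
    render_lattice_volume(lat14, voxel_size = 8, snr = 0.5, wedge = 60, seed = s))
  expect_equal(classify_pf_number(vols)$n_pf, 14L)

  ## pure noise is unclassified
  set.seed(1)
  vn <- mt_volume(array(rnorm(48 * 48 * 64), c(48, 48, 64)), 8, c(-188, -188, 0))
  expect_true(is.na(classify_pf_number(vn)$n_pf))
})

test_that("decoration profiling calls the seam and a four-junction layout", {
  lat <- mt_lattice(13, 12)
  vd <- render_lattice_volume(lat, decorations = data.frame(junction = 13),
                              voxel_size = 8, snr = 0.3, wedge = 60, seed = 21)
  dp <- junction_decoration_profile(vd, lat)
  expect_equal(which(dp$called), 13L)
  cs <- call_seam_binder(dp)
  expect_true(cs$unique)
  expect_equal(cs$junction, c(13L, 1L))

  ## tip-CP-like wedge layout: junctions 13/1, 11/12, 10/11, 5/6
  layout <- data.frame(junction = c(13L, 11L, 10L, 5L))
  vm <- render_lattice_volume(lat, decorations = layout,
                              voxel_size = 8, snr = 0.3, wedge = 60, seed = 22)
  dpm <- junction_decoration_profile(vm, lat)
  expect_setequal(which(dpm$called), c(13L, 11L, 10L, 5L))
  csm <- call_seam_binder(dpm)
  expect_false(csm$unique)
  expect_length(csm$multi_site_junctions, 4L)

  ## undecorated: nothing called, empty call
  vu <- render_lattice_volume(lat, voxel_size = 8, snr = 0.3, wedge = 60, seed = 23)
  dpu <- junction_decoration_profile(vu, lat)
  expect_equal(sum(dpu$called), 0L)
  csu <- call_seam_binder(dpu)
  expect_null(csu$junction)
  expect_false(csu$unique)

  ## frame mismatch is rejected
  shifted <- vd; shifted$origin <- shifted$origin + 5000
  expect_error(junction_decoration_profile(shifted, lat), "frame mismatch")
})

test_that("decoration z-score grows with occupancy", {
  lat <- mt_lattice(13, 12)
  z_at <- vapply(c(0.3, 0.6, 1.0), function(occ) {
    mean(vapply(31:34, function(s) {
      v <- render_lattice_volume(lat,
        decorations = data.frame(junction = 13, occupancy = occ),
        voxel_size = 8, snr = 0.5, wedge = 60, seed = s)
      junction_decoration_profile(v, lat)$zscore[13]
    }, 0))
  }, 0)
  expect_true(all(diff(z_at) > 0))
})
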