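test_that("filament axis recovers the lattice axis and is equivariant", {
  lat <- mt_lattice(13, 5)
  ax <- fit_filament_axis(lat)
  expect_equal(abs(ax$direction[3]), 1, tolerance = 1e-9)

  ## rigid rotation rotates the axis with the cloud
  rs <- rigid_transform(lat$sites)
  axr <- fit_filament_axis(rs)
  Rz <- matrix(c(cos(0.7), -sin(0.7), 0, sin(0.7), cos(0.7), 0, 0, 0, 1), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(1.1), -sin(1.1), 0, sin(1.1), cos(1.1)), 3, byrow = TRUE)
  expected <- as.numeric((Rx %*% Rz) %*% c(0, 0, 1))
  expect_lt(min(sqrt(sum((axr$direction - expected)^2)),
                sqrt(sum((axr$direction + expected)^2))), 1e-6)

  ## coplanar input is rejected
  flat <- lat$sites[lat$sites$repeat_index == 0 & lat$sites$chain == "alpha", ]
  expect_error(fit_filament_axis(transform(flat, z = 0)), "degenerate|repeats")
})

test_that("axis fit stays within 0.5 degree under monomer jitter", {
  set.seed(421)
  errs <- replicate(60, {
    lat <- mt_lattice(13, 6)
    lat$sites[, c("x", "y", "z")] <- lat$sites[, c("x", "y", "z")] +
      rnorm(nrow(lat$sites) * 3, sd = 0.2)
    ax <- fit_filament_axis(lat$sites)
    acos(min(1, abs(ax$direction[3]))) * 180 / pi
  })
  expect_true(all(errs < 0.5))
})

test_that("inter-PF angles reproduce 360/N on ideal lattices", {
  for (n in c(11, 13, 14, 15)) {
    prof <- compute_inter_pf_angles(mt_lattice(n, 4))
    expect_equal(prof$angle_deg, rep(360 / n, n), tolerance = 1e-6)
    expect_equal(sum(prof$angle_deg), 360, tolerance = 1e-6)
  }
})

test_that("angle measurement is invariant under rigid motion", {
  lat <- mt_lattice(13, 5, angle_profile = fixture_profile())
  prof0 <- compute_inter_pf_angles(lat)
  prof1 <- compute_inter_pf_angles(rigid_transform(lat$sites))
  expect_equal(prof1$angle_deg, prof0$angle_deg, tolerance = 1e-6)
  expect_equal(prof0$angle_deg[11], 35.3, tolerance = 0.01)
})

test_that("build-measure round trip recovers random profiles", {
  set.seed(77)
  for (rep in 1:10) {
    a <- runif(13, 0.5, 1.5); a <- a / sum(a) * 360
    prof <- pf_angle_profile(a)
    meas <- compute_inter_pf_angles(mt_lattice(13, 4, angle_profile = prof))
    expect_equal(meas$angle_deg, a, tolerance = 1e-6)
    expect_equal(sum(meas$angle_deg), 360, tolerance = 1e-6)
  }
})

test_that("a repeat with missing protofilaments is excluded with a warning", {
  lat <- mt_lattice(13, 5)
  broken <- lat$sites[!(lat$sites$repeat_index == 2 & lat$sites$pf == 7), ]
  expect_warning(prof <- compute_inter_pf_angles(broken), "missing")
  expect_equal(prof$angle_deg, rep(360 / 13, 13), tolerance = 1e-6)
  ## fewer than 3 usable repeats is an error
  few <- lat$sites[lat$sites$repeat_index < 3, ]
  few <- few[!(few$repeat_index == 0 & few$pf == 1), ]
  expect_warning(expect_error(compute_inter_pf_angles(few), "repeats"))
})

test_that("junction classification finds the one seam, none, or two", {
  ## canonical B-lattice: exactly one heterotypic junction at (13, 1)
  jt <- classify_junctions(mt_lattice(13, 5))
  expect_equal(sum(jt$is_seam), 1L)
  expect_equal(c(jt$pf_i[jt$is_seam], jt$pf_j[jt$is_seam]), c(13L, 1L))
  expect_equal(jt$axial_offset[jt$is_seam], 12 / 13, tolerance = 1e-9)

  ## seamless closure
  expect_equal(sum(classify_junctions(mt_lattice(13, 5, start_stagger = 8))$is_seam), 0L)

  ## two engineered half-dimer phase slips: two junctions flagged
  ts <- two_slip_lattice()
  jt2 <- classify_junctions(ts)
  expect_equal(sum(jt2$is_seam), 2L)
  expect_setequal(jt2$pf_i[jt2$is_seam], c(3L, 9L))
})

test_that("seam detection matches the exhaustive oracle and survives rotation", {
  set.seed(5)
  for (n in c(11, 14)) {
    for (a in sample(1:n, 3)) {
      lat <- mt_lattice(n, 5, seed_pf = a)
      jt <- classify_junctions(lat)
      orc <- oracle_junctions(lat$sites)
      expect_equal(jt$is_seam, orc$het)
      expect_equal(c(jt$pf_i[jt$is_seam], jt$pf_j[jt$is_seam]), lat$seam_junction)
    }
  }
  lat <- mt_lattice(13, 5)
  jtr <- classify_junctions(rigid_transform(lat$sites))
  expect_equal(c(jtr$pf_i[jtr$is_seam], jtr$pf_j[jtr$is_seam]), c(13L, 1L))
})

test_that("protofilament assignment counts and labels clusters", {
  for (n in c(13, 14)) {
    lat <- mt_lattice(n, 6)
    mids <- aggregate(cbind(x, y, z) ~ pf + repeat_index, data = lat$sites, FUN = mean)
    ap <- assign_protofilaments(mids[, c("x", "y", "z")])
    expect_equal(ap$n_pf, n)
    ## labels match the originals up to a cyclic shift
    shift <- unique((mids$pf - ap$labels) %% n)
    expect_length(shift, 1L)
  }
})

test_that("protofilament counting tolerates jitter", {
  set.seed(99)
  lat <- mt_lattice(13, 6)
  mids <- aggregate(cbind(x, y, z) ~ pf + repeat_index, data = lat$sites, FUN = mean)
  hits <- sum(replicate(40, {
    pts <- as.matrix(mids[, c("x", "y", "z")]) + rnorm(nrow(mids) * 3, sd = 0.3)
    colnames(pts) <- c("x", "y", "z")
    n <- try(assign_protofilaments(pts)$n_pf, silent = TRUE)
    isTRUE(n == 13)
  }))
  expect_gte(hits, 39)
})
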