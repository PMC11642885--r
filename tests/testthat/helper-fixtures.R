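## shared test fixtures, built in code

## rigidly transform a site table (rotation about z then x, plus shift)
rigid_transform <- function(sites, theta = 0.7, phi = 1.1, shift = c(5, -3, 2)) {
  Rz <- matrix(c(cos(theta), -sin(theta), 0,
                 sin(theta),  cos(theta), 0,
                 0, 0, 1), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0,
                 0, cos(phi), -sin(phi),
                 0, sin(phi),  cos(phi)), 3, byrow = TRUE)
  xyz <- as.matrix(sites[, c("x", "y", "z")]) %*% t(Rx %*% Rz)
  sites[, c("x", "y", "z")] <- sweep(xyz, 2, shift, "+")
  sites
}

## the bundled non-uniform angle profile (junction 11/12 at 35.3 deg)
fixture_profile <- function() {
  path <- system.file("extdata", "tipcp_c2_like_profile.csv", package = "mtseam")
  df <- read.csv(path)
  pf_angle_profile(df$angle_deg)
}

## a lattice with two half-dimer phase slips (two heterotypic junctions):
## start from a seamless tube and lift a contiguous arc of PFs by half a
## dimer
two_slip_lattice <- function(n_pf = 13, n_repeats = 5, arc = 4:9) {
  lat <- mt_lattice(n_pf, n_repeats, start_stagger = 8.0)
  lift <- lat$sites$pf %in% arc
  lat$sites$z[lift] <- lat$sites$z[lift] + lat$dimer_rise / 2
  lat
}

## exhaustive all-pairs nearest-neighbour junction oracle (no axial
## window, no shortcuts): for each monomer of PF i, the nearest monomer
## on PF j decides the vote
oracle_junctions <- function(sites, dimer_rise = 8) {
  pfs <- sort(unique(sites$pf))
  n <- length(pfs)
  az <- vapply(pfs, function(p) {
    atan2(mean(sites$y[sites$pf == p]), mean(sites$x[sites$pf == p]))
  }, 0)
  ord <- pfs[order(az)]
  steps <- (diff(match(ord, pfs)) %% n)
  if (sum(steps == n - 1) > sum(steps == 1)) ord <- rev(ord)
  out <- data.frame(pf_i = integer(0), pf_j = integer(0), het = logical(0))
  for (k in seq_len(n)) {
    pi_ <- ord[k]; pj_ <- ord[if (k == n) 1 else k + 1]
    si <- sites[sites$pf == pi_, ]; sj <- sites[sites$pf == pj_, ]
    votes <- vapply(seq_len(nrow(si)), function(m) {
      d <- sqrt((sj$x - si$x[m])^2 + (sj$y - si$y[m])^2 + (sj$z - si$z[m])^2)
      ## ignore partners more than one repeat away (finite-lattice edges)
      d[abs(sj$z - si$z[m]) > dimer_rise] <- Inf
      sj$chain[which.min(d)] != si$chain[m]
    }, TRUE)
    out <- rbind(out, data.frame(pf_i = pi_, pf_j = pj_,
                                 het = mean(votes) > 0.5))
  }
  out[order(out$pf_i), ]
}
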