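test_that("tip tracing inverts noise-free rendering", {
  tr <- simulate_dynamics(di_params(), seed = 5)
  ky <- render_kymograph(tr, psf_sigma = 0, snr = Inf)
  tt <- trace_tip(ky, median_frames = 1)
  truth <- tr$frames$tip_um / ky$pixel_size
  expect_true(all(abs(tt$tip_px - truth) <= 1))
  expect_equal(attr(tt, "provenance"), "auto")

  ## with the default conditional despike the corner frames stay exact too
  tt3 <- trace_tip(ky)
  expect_true(all(abs(tt3$tip_px - truth) <= 1))
})

test_that("tip tracing stays within 2 px at SNR 3 away from corners", {
  set.seed(41)
  frac_ok <- replicate(25, {
    tr <- simulate_dynamics(di_params(), seed = sample.int(1e6, 1))
    ky <- render_kymograph(tr, psf_sigma = 1, snr = 3, seed = sample.int(1e6, 1))
    tt <- trace_tip(ky)
    truth <- tr$frames$tip_um / ky$pixel_size
    ## corner frames (phase switches) are excluded: the 3-frame window
    ## necessarily blends them
    corner <- c(FALSE, abs(diff(sign(diff(truth)))) > 0, FALSE)
    keep <- !corner
    mean(abs(tt$tip_px - truth)[keep] <= 2)
  })
  expect_gt(mean(frac_ok), 0.95)
})

test_that("blank images are rejected", {
  expect_error(trace_tip(matrix(0, 50, 100), seed_extent = 10), "no microtubule")
  set.seed(1)
  expect_error(trace_tip(matrix(rnorm(5000), 50, 100), seed_extent = 10),
               "no microtubule")
  expect_error(trace_tip(matrix(1, 5, 100), seed_extent = 10), "10 frames")
})

test_that("segmentation recovers constructed phases exactly", {
  x <- c(rep(0, 10), cumsum(rep(2, 20)), rev(seq(0, 36, by = 6)))
  tt <- tip_trace(x, pixel_size = 0.1, frame_interval = 10)
  seg <- segment_phases(tt)
  expect_equal(seg$phases$kind, c("nucleating", "growth", "shrinkage"))
  expect_equal(seg$phases$slope_px_per_frame[2], 2)
  expect_equal(seg$phases$slope_px_per_frame[3], -6)
  expect_equal(seg$first_triangle$growth, 2L)
  expect_equal(seg$first_triangle$shrinkage, 3L)
  expect_false(seg$first_triangle$censored)

  ds <- compute_dynamics_summary(seg)
  ## slope 2 px/frame, 0.1 um/px, 10 s/frame -> 1.2 um/min
  expect_equal(ds$growth_rate, 1.2)
  expect_equal(ds$shrink_rate, 3.6)
  expect_equal(ds$length_um, 4.0)

  ## monotone growth to the movie end: censored triangle
  xm <- c(rep(0, 10), cumsum(rep(2, 30)))
  segm <- segment_phases(tip_trace(xm, 0.1, 10))
  expect_true(segm$first_triangle$censored)
  dsm <- compute_dynamics_summary(segm)
  expect_true(is.na(dsm$shrink_rate))

  ## no growth at all: empty triangle
  segf <- segment_phases(tip_trace(rep(0, 30), 0.1, 10))
  expect_true(is.na(segf$first_triangle$growth))
  expect_true(is.na(compute_dynamics_summary(segf)$growth_rate))
})

test_that("nucleation time follows the mix-frame convention", {
  ## growth starts at frame 32, mix at frame 2, 10 s/frame -> 5.0 min
  x <- c(rep(0, 31), cumsum(rep(2, 30)), rev(seq(0, 58, by = 6)))
  seg <- segment_phases(tip_trace(x, 0.1, 10))
  ds <- compute_dynamics_summary(seg, mix_frame = 2)
  expect_equal(ds$nucleation_time_min, 5.0)
})

test_that("the 5-pixel rescue rule separates true rescues", {
  mk <- function(rescue_at) {
    x <- c(rep(0, 5), cumsum(rep(4, 15)),                 # up to 60 px
           rev(seq(rescue_at, 54, by = 6)),               # down to the rescue point
           rescue_at + cumsum(rep(4, 10)))                # regrow
    tip_trace(x, 0.1, 10)
  }
  seg10 <- segment_phases(mk(12))
  ev10 <- classify_rescue(seg10)
  expect_equal(nrow(ev10), 1L)
  expect_true(ev10$is_true_rescue[1])

  seg3 <- segment_phases(mk(3))
  ev3 <- classify_rescue(seg3)
  expect_equal(nrow(ev3), 1L)
  expect_true(ev3$rescued[1])
  expect_false(ev3$is_true_rescue[1])

  ## shrinkage to the seed without regrowth: an event, not a true rescue
  xs <- c(rep(0, 5), cumsum(rep(4, 15)), rev(seq(0, 54, by = 6)), rep(0, 10))
  evs <- classify_rescue(segment_phases(tip_trace(xs, 0.1, 10)))
  expect_equal(nrow(evs), 1L)
  expect_false(evs$is_true_rescue[1])

  ## no shrinkage: no events
  evn <- classify_rescue(segment_phases(tip_trace(c(rep(0, 5), cumsum(rep(2, 30))), 0.1, 10)))
  expect_equal(nrow(evn), 0L)
})

test_that("rescue probability is true rescues over all events", {
  ev <- data.frame(is_true_rescue = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(rescue_probability(ev)$estimate, 0.4)
  expect_equal(rescue_probability(data.frame(is_true_rescue = rep(TRUE, 3)))$estimate, 1.0)
  ## replicate averaging and invariance to event order
  ev$replicate <- c(1, 1, 1, 2, 2)
  rp <- rescue_probability(ev)
  expect_equal(unname(rp$per_replicate), c(2 / 3, 0))
  expect_equal(rp$estimate, 1 / 3)
  shuf <- ev[c(4, 1, 5, 3, 2), ]
  expect_equal(rescue_probability(shuf)$estimate, rp$estimate)
  expect_error(rescue_probability(ev[0, ]), "no events")
})

test_that("dose-response aggregation and unit safety", {
  one <- data.frame(concentration = 0, length_um = 3, lifetime_min = 4,
                    growth_rate = 1.2, shrink_rate = 6, nucleation_time_min = 2)
  tab <- aggregate_conditions(rbind(one, one, one))
  expect_equal(tab$n, 3L)
  expect_equal(tab$sd_length_um, 0)
  expect_equal(tab$mean_growth_rate, 1.2)

  ## doubling pixel_size doubles lengths and rates, leaves times alone
  x <- c(rep(0, 10), cumsum(rep(2, 20)), rev(seq(0, 36, by = 6)))
  seg <- segment_phases(tip_trace(x))
  d1 <- compute_dynamics_summary(seg, pixel_size = 0.1, frame_interval = 10)
  d2 <- compute_dynamics_summary(seg, pixel_size = 0.2, frame_interval = 10)
  expect_equal(d2$length_um, 2 * d1$length_um)
  expect_equal(d2$growth_rate, 2 * d1$growth_rate)
  expect_equal(d2$shrink_rate, 2 * d1$shrink_rate)
  expect_equal(d2$lifetime_min, d1$lifetime_min)
  expect_equal(d2$nucleation_time_min, d1$nucleation_time_min)
})

test_that("manual CSV traces are first-class inputs", {
  x <- c(rep(0, 10), cumsum(rep(2, 20)), rev(seq(0, 36, by = 6)))
  tt <- tip_trace(x, pixel_size = 0.1, frame_interval = 10)
  f <- tempfile(fileext = ".csv")
  write_tip_trace(tt, f)
  tt2 <- read_tip_trace(f)
  expect_equal(attr(tt2, "provenance"), "manual_csv")
  ds <- compute_dynamics_summary(segment_phases(tt2))
  expect_equal(ds$growth_rate, 1.2)
})
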